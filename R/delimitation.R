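#' Pipeline configuration
#'
#' Collects the tunable parameters of the delimitation pipeline. All have
#' field-conventional defaults and every report echoes the configuration
#' used.
#'
#' @param theta haplogroup clustering threshold (proportion, default 0.02).
#' @param delta karyotype species-level count gap (integer, default 3).
#' @param alpha significance level for the association test (default 0.05).
#' @param n_permutations permutations for sampled association tests
#'   (default 9999).
#' @param radius_km locality merge radius for sympatry detection
#'   (default 0: exact locality match).
#' @param seed integer seed used for all randomized steps.
#' @return A list of class `run_config`.
#' @export
run_config <- function(theta = 0.02, delta = 3L, alpha = 0.05,
                       n_permutations = 9999, radius_km = 0, seed = 1L) {
  stopifnot(theta >= 0, theta <= 1, delta >= 1, alpha > 0, alpha < 1,
            n_permutations >= 99, radius_km >= 0)
  structure(list(theta = theta, delta = as.integer(delta), alpha = alpha,
                 n_permutations = as.integer(n_permutations),
                 radius_km = radius_km, seed = as.integer(seed)),
            class = "run_config")
}

.RELATIONS <- c("indistinguishable", "minor_count_difference",
                "fixed_count_difference", "structure_difference")
.DECISIONS <- c("distinct_species", "conspecific_subspecies", "synonym",
                "single_polymorphic_species", "unresolved")

#' Taxonomic decision from combined evidence
#'
#' The rule engine converting karyotype, barcode, sympatry and
#' heterozygote evidence for one pair of groups into a taxonomic verdict.
#' Rules are tried in a fixed order and exactly one fires:
#'
#' * **R1** sympatric, significant association with one-to-one stable
#'   karyotype-haplogroup combinations, and no chromosomal heterozygotes ->
#'   `distinct_species` (the sympatric biological-species criterion).
#' * **R2** sympatric, but heterozygotes observed or the association is not
#'   significant -> `single_polymorphic_species` (markers in linkage
#'   equilibrium are intra-population variation).
#' * **R3** allopatric with a fixed karyotype difference (structure
#'   difference or count gap >= delta) -> `distinct_species`; when the
#'   groups are nevertheless *not* barcode-differentiated the verdict is
#'   flagged as mitochondrial introgression (barcode identity between
#'   deeply differentiated chromosomal lineages).
#' * **R4** allopatric, karyotypes indistinguishable or differing by a
#'   minor count gap, barcodes differentiated -> `conspecific_subspecies`
#'   (differentiated phylogeographic sublineages).
#' * **R5** allopatric, karyotypes indistinguishable, barcodes not
#'   differentiated -> `synonym` (no phylogeographic sublineage to name).
#' * **R6** anything else -> `unresolved`.
#'
#' @param evidence a list with fields `sympatric` (logical),
#'   `karyo_relation` (one of the [compare_groups()] relations),
#'   `association_p` (p-value, `NA`/`NULL` when allopatric), `one_to_one`
#'   (logical, may be `NA` when allopatric), `heterozygotes` (logical),
#'   `barcode_differentiated` (logical, `NA` when a group lacks
#'   sequences), `n_diagnostic_sites` (integer).
#' @param alpha significance level for the association test.
#' @return A list of class `verdict` with `decision`, `rule_fired`,
#'   `introgression_flag` and the `evidence` record.
#' @export
decide <- function(evidence, alpha = 0.05) {
  e <- evidence
  stopifnot(is.logical(e$sympatric), e$karyo_relation %in% .RELATIONS)
  p <- if (is.null(e$association_p)) NA_real_ else e$association_p
  if (e$sympatric && is.na(p)) {
    stop("inconsistent evidence: sympatric pair without an association p-value",
         call. = FALSE)
  }
  bd <- if (is.null(e$barcode_differentiated)) NA else e$barcode_differentiated
  het <- isTRUE(e$heterozygotes)
  introgression <- FALSE
  if (e$sympatric && !is.na(p) && p < alpha && isTRUE(e$one_to_one) && !het) {
    decision <- "distinct_species"; rule <- "R1"
  } else if (e$sympatric && (het || p >= alpha)) {
    decision <- "single_polymorphic_species"; rule <- "R2"
  } else if (!e$sympatric &&
             e$karyo_relation %in% c("structure_difference", "fixed_count_difference")) {
    decision <- "distinct_species"; rule <- "R3"
    introgression <- isFALSE(bd)
  } else if (!e$sympatric &&
             e$karyo_relation %in% c("indistinguishable", "minor_count_difference") &&
             isTRUE(bd)) {
    decision <- "conspecific_subspecies"; rule <- "R4"
  } else if (!e$sympatric && e$karyo_relation == "indistinguishable" &&
             isFALSE(bd)) {
    decision <- "synonym"; rule <- "R5"
  } else {
    decision <- "unresolved"; rule <- "R6"
  }
  structure(list(decision = decision, rule_fired = rule,
                 introgression_flag = introgression, evidence = e),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("verdict: %s (rule %s%s)\n", x$decision, x$rule_fired,
              if (x$introgression_flag) ", mitochondrial introgression suspected" else ""))
  invisible(x)
}

#' Barcode differentiation between two groups
#'
#' Two groups are barcode-differentiated when they show at least one fixed
#' diagnostic substitution, or when the minimum between-group p-distance
#' exceeds the haplogroup threshold `theta` (the distance stand-in for
#' sublineage monophyly).
#'
#' @param aln a [dna_alignment].
#' @param group_a,group_b sequence id sets.
#' @param dm distance matrix over (at least) the two groups.
#' @param theta distance threshold, default 0.02.
#' @return A list with `differentiated` (logical) and `n_diagnostic_sites`.
#' @export
barcode_differentiation <- function(aln, group_a, group_b, dm, theta = 0.02) {
  sites <- diagnostic_sites(aln, group_a, group_b)
  mind <- min_group_distance(dm, group_a, group_b)
  list(differentiated = nrow(sites) > 0L || (!is.na(mind) && mind > theta),
       n_diagnostic_sites = nrow(sites),
       min_distance = mind)
}

#' Run the full delimitation pipeline
#'
#' End-to-end analysis: reads the karyotype table, aligned barcodes and
#' (optionally) the locality table; clusters barcodes into haplogroups and
#' karyotypes into classes; forms putative groups as sets of samples
#' sharing a (karyotype class, haplogroup) combination; detects sympatry;
#' and adjudicates every group pair with [decide()].
#'
#' Samples may carry a karyotype only, a sequence only, or both; at least
#' one sample must carry both. Karyotype-only samples join the group with
#' the same karyotype class (preferring one present at their locality);
#' sequence-only samples join a group by haplogroup when that is
#' unambiguous. Verdicts involving groups without sequences are annotated
#' `karyotype_only`.
#'
#' @param karyotype path to the karyotype TSV, or a data.frame.
#' @param fasta path to the aligned FASTA, or a [dna_alignment].
#' @param localities optional path to a locality TSV, or a data.frame.
#' @param config a [run_config()].
#' @return A list of class `delimitation_result` with elements `groups`
#'   (data.frame of group summaries), `assignments` (per-sample group,
#'   karyotype class and haplogroup), `verdicts` (one row per group pair),
#'   `associations` (per-site association results), `tree` (NJ tree over
#'   samples with sequences, `NULL` below 3), `sympatry`, `haplogroups`
#'   and `config`.
#' @export
run_pipeline <- function(karyotype, fasta, localities = NULL,
                         config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  karyo <- if (is.character(karyotype)) read_karyotype_table(karyotype) else karyotype
  aln <- if (is.character(fasta)) read_alignment(fasta) else fasta
  locs <- if (is.character(localities)) read_locality_table(localities) else localities

  joint <- intersect(karyo$sample_id, aln$ids)
  if (length(joint) == 0L) {
    stop("no sample carries both a karyotype and a sequence; the pipeline ",
         "requires at least some joint samples", call. = FALSE)
  }

  dm <- distance_matrix(aln)
  hap <- cluster_haplogroups(dm, theta = config$theta)
  kclass <- karyo_classes(karyo, delta = config$delta)

  asg <- .assign_groups(karyo, aln, kclass, hap)
  groups <- unique(asg$group_id)

  # per-group structures
  summaries <- list()
  seq_ids <- list()
  obs_of <- list()
  for (g in groups) {
    ids <- asg$sample_id[asg$group_id == g]
    obs <- karyo[karyo$sample_id %in% ids, , drop = FALSE]
    obs_of[[g]] <- obs
    summaries[[g]] <- if (nrow(obs)) summarize_group(obs, g) else NULL
    seq_ids[[g]] <- intersect(ids, aln$ids)
  }

  sym_records <- asg[!is.na(asg$locality_id),
                     c("sample_id", "group_id", "locality_id")]
  sym <- detect_sympatry(sym_records, localities = locs,
                         radius_km = config$radius_km)

  # per-site association tests over all samples with both markers
  assoc <- .site_associations(asg, sym, config)

  verdicts <- .adjudicate_pairs(groups, summaries, seq_ids, obs_of, asg,
                                sym, assoc, aln, dm, config)

  tree <- if (length(aln$ids) >= 3L) neighbor_joining(dm) else NULL

  structure(list(
    groups = .summaries_df(summaries, asg),
    assignments = asg,
    verdicts = verdicts,
    associations = assoc,
    tree = tree,
    sympatry = sym,
    haplogroups = hap,
    config = config
  ), class = "delimitation_result")
}

# Group formation: joint samples keyed by (karyotype class, haplogroup);
# marker-incomplete samples attached as documented in run_pipeline().
.assign_groups <- function(karyo, aln, kclass, hap) {
  all_ids <- union(karyo$sample_id, aln$ids)
  df <- data.frame(
    sample_id = all_ids,
    karyo_class = unname(kclass[all_ids]),
    haplogroup = unname(hap[all_ids]),
    locality_id = karyo$locality_id[match(all_ids, karyo$sample_id)],
    stringsAsFactors = FALSE
  )
  key <- ifelse(!is.na(df$karyo_class) & !is.na(df$haplogroup),
                paste(df$karyo_class, df$haplogroup, sep = "|"), NA_character_)
  joint_keys <- unique(key[!is.na(key)])
  gid <- stats::setNames(paste0("G", seq_along(joint_keys)), joint_keys)
  df$group_id <- unname(gid[key])
  key_class <- sub("\\|.*$", "", joint_keys)
  key_hap <- sub("^.*\\|", "", joint_keys)
  # karyotype-only samples: same class; prefer a group seen at the same locality
  for (i in which(is.na(df$group_id) & !is.na(df$karyo_class))) {
    cand <- joint_keys[key_class == df$karyo_class[i]]
    if (length(cand) > 1L && !is.na(df$locality_id[i])) {
      here <- vapply(cand, function(k) {
        any(df$locality_id[which(df$group_id == gid[[k]])] %in% df$locality_id[i])
      }, TRUE)
      if (any(here)) cand <- cand[here]
    }
    df$group_id[i] <- if (length(cand) >= 1L) gid[[cand[[1L]]]] else {
      paste0("K_", df$karyo_class[i])
    }
  }
  # sequence-only samples: unambiguous haplogroup match, else own group
  for (i in which(is.na(df$group_id) & !is.na(df$haplogroup))) {
    cand <- joint_keys[key_hap == df$haplogroup[i]]
    df$group_id[i] <- if (length(cand) == 1L) gid[[cand]] else {
      paste0("S_", df$haplogroup[i])
    }
  }
  df
}

.site_associations <- function(asg, sym, config) {
  usable <- asg[!is.na(asg$karyo_class) & !is.na(asg$haplogroup) &
                  !is.na(asg$locality_id), , drop = FALSE]
  out <- list()
  for (s in names(sym$site_groups)) {
    rows <- usable[sym$site_of[usable$locality_id] == s, , drop = FALSE]
    if (nrow(rows) < 2L) next
    # a single-species site carries no marker contrast to test
    if (length(unique(rows$karyo_class)) == 1L &&
        length(unique(rows$haplogroup)) == 1L) next
    out[[s]] <- association_test(rows$karyo_class, rows$haplogroup,
                                 n_permutations = config$n_permutations,
                                 seed = config$seed, locality_id = s)
  }
  out
}

.adjudicate_pairs <- function(groups, summaries, seq_ids, obs_of, asg, sym,
                              assoc, aln, dm, config) {
  rows <- list()
  if (length(groups) < 2L) return(.empty_verdicts())
  pairs <- utils::combn(sort(groups), 2L)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    sa <- summaries[[a]]; sb <- summaries[[b]]
    karyotype_only <- length(seq_ids[[a]]) == 0L || length(seq_ids[[b]]) == 0L
    karyo_rel <- if (!is.null(sa) && !is.null(sb)) compare_groups(sa, sb, config$delta) else NULL
    sympatric <- is_sympatric(sym, a, b)
    # association evidence: significance comes from the site-level test
    # (pooling the whole community for power); the stable-combination flag
    # is pair-level — the two groups must differ in BOTH markers, i.e.
    # distinct karyotype classes bound to distinct haplogroups.
    p <- NA_real_; one <- NA
    if (sympatric) {
      shared <- names(Filter(function(gs) all(c(a, b) %in% gs), sym$site_groups))
      ps <- vapply(shared, function(s) {
        if (!is.null(assoc[[s]])) assoc[[s]]$p_value else NA_real_
      }, 1)
      if (any(!is.na(ps))) p <- min(ps, na.rm = TRUE)
      one <- .pair_one_to_one(asg, a, b)
    }
    bd <- list(differentiated = NA, n_diagnostic_sites = NA_integer_,
               min_distance = NA_real_)
    if (!karyotype_only) {
      bd <- barcode_differentiation(aln, seq_ids[[a]], seq_ids[[b]], dm,
                                    theta = config$theta)
    }
    het <- any(obs_of[[a]]$multivalents_observed %in% TRUE) ||
      any(obs_of[[b]]$multivalents_observed %in% TRUE)
    evidence <- list(
      sympatric = sympatric,
      karyo_relation = if (!is.null(karyo_rel)) karyo_rel$relation else "indistinguishable",
      count_gap = if (!is.null(karyo_rel)) karyo_rel$count_gap else NA_integer_,
      low_confidence = if (!is.null(karyo_rel)) karyo_rel$low_confidence else NA,
      association_p = p,
      one_to_one = one,
      heterozygotes = het,
      barcode_differentiated = bd$differentiated,
      n_diagnostic_sites = bd$n_diagnostic_sites,
      min_distance = bd$min_distance
    )
    v <- decide(evidence, alpha = config$alpha)
    rows[[k]] <- data.frame(
      group_a = a, group_b = b, decision = v$decision,
      rule_fired = v$rule_fired, introgression_flag = v$introgression_flag,
      sympatric = sympatric, karyo_relation = evidence$karyo_relation,
      count_gap = evidence$count_gap,
      association_p = p, one_to_one = one, heterozygotes = het,
      barcode_differentiated = bd$differentiated,
      n_diagnostic_sites = bd$n_diagnostic_sites,
      min_distance = bd$min_distance,
      karyotype_only = karyotype_only,
      low_confidence = evidence$low_confidence,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

.pair_one_to_one <- function(asg, a, b) {
  ka <- unique(stats::na.omit(asg$karyo_class[asg$group_id == a]))
  kb <- unique(stats::na.omit(asg$karyo_class[asg$group_id == b]))
  ha <- unique(stats::na.omit(asg$haplogroup[asg$group_id == a]))
  hb <- unique(stats::na.omit(asg$haplogroup[asg$group_id == b]))
  if (!length(ka) || !length(kb) || !length(ha) || !length(hb)) return(NA)
  length(intersect(ka, kb)) == 0L && length(intersect(ha, hb)) == 0L
}

.empty_verdicts <- function() {
  data.frame(group_a = character(), group_b = character(),
             decision = character(), rule_fired = character(),
             introgression_flag = logical(), sympatric = logical(),
             karyo_relation = character(), count_gap = integer(),
             association_p = numeric(), one_to_one = logical(),
             heterozygotes = logical(), barcode_differentiated = logical(),
             n_diagnostic_sites = integer(), min_distance = numeric(),
             karyotype_only = logical(), low_confidence = logical(),
             stringsAsFactors = FALSE)
}

.summaries_df <- function(summaries, asg) {
  rows <- lapply(names(summaries), function(g) {
    s <- summaries[[g]]
    labels <- NA_character_
    if (is.null(s)) {
      return(data.frame(group_id = g, n_samples = sum(asg$group_id == g),
                        exact_min = NA_integer_, exact_max = NA_integer_,
                        approx_min = NA_integer_, approx_max = NA_integer_,
                        modal_count = NA_integer_, structure = NA_character_,
                        any_multivalents = NA, stringsAsFactors = FALSE))
    }
    data.frame(group_id = g, n_samples = s$n_samples,
               exact_min = s$exact_min, exact_max = s$exact_max,
               approx_min = s$approx_min, approx_max = s$approx_max,
               modal_count = s$modal_count, structure = s$structure,
               any_multivalents = s$any_multivalents,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.delimitation_result <- function(x, ...) {
  cat(sprintf("delimitation result: %d group(s), %d pairwise verdict(s)\n",
              nrow(x$groups), nrow(x$verdicts)))
  if (nrow(x$verdicts)) {
    print(x$verdicts[, c("group_a", "group_b", "decision", "rule_fired",
                         "introgression_flag")])
  }
  invisible(x)
}

#' Write the delimitation report
#'
#' Writes, under `dir`: `groups.tsv` (per-group karyotype summaries),
#' `verdicts.tsv` (one row per group pair with decision, rule and
#' evidence), `associations.tsv` (per-site association tests) and
#' `tree.nwk` (the NJ tree, when available). Every TSV starts with `#`
#' header lines echoing the package version, configuration and seed.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_delimitation_report <- function(result, dir) {
  stopifnot(inherits(result, "delimitation_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- .report_header(result$config)
  .write_tsv_with_header(result$groups, file.path(dir, "groups.tsv"), hdr)
  .write_tsv_with_header(result$verdicts, file.path(dir, "verdicts.tsv"), hdr)
  assoc_df <- do.call(rbind, lapply(result$associations, function(a) {
    data.frame(site = a$locality_id, n_classes = nrow(a$table),
               n_haplogroups = ncol(a$table), statistic = a$statistic,
               p_value = a$p_value, method = a$method,
               one_to_one = a$one_to_one, stringsAsFactors = FALSE)
  }))
  if (is.null(assoc_df)) {
    assoc_df <- data.frame(site = character(), n_classes = integer(),
                           n_haplogroups = integer(), statistic = numeric(),
                           p_value = numeric(), method = character(),
                           one_to_one = logical())
  }
  .write_tsv_with_header(assoc_df, file.path(dir, "associations.tsv"), hdr)
  if (!is.null(result$tree)) {
    write_newick(result$tree, file.path(dir, "tree.nwk"))
  }
  invisible(dir)
}

.report_header <- function(config) {
  c(sprintf("# karyodelim %s",
            as.character(utils::packageVersion("karyodelim"))),
    sprintf("# config: theta=%g delta=%d alpha=%g n_permutations=%d radius_km=%g seed=%d",
            config$theta, config$delta, config$alpha, config$n_permutations,
            config$radius_km, config$seed))
}

.write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
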