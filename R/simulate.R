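#' Configuration for a synthetic cryptic-species-complex dataset
#'
#' Defines the ground truth of a simulated complex: per-species haploid
#' chromosome counts (with an intraspecific uniform integer spread),
#' marker-bivalent structures, barcode divergence as shared diagnostic
#' columns on a star phylogeny, within-species per-site mutation noise,
#' optional mitochondrial introgression (whole-barcode capture of the
#' donor's haplotype by the recipient, as seen when chromosomally distinct
#' species share barcodes), and a sympatric/allopatric locality layout.
#'
#' The defaults emulate a four-species community like the one observed in
#' complete sympatry at Gnishik: haploid counts 78+/-1, 79, 74+/-1 and
#' 32+/-2 with structures `1L+1M`, `1L+0M`, `2L+2M` and `0L+0M`; 658 bp
#' barcodes; 20 fixed diagnostic differences per species pair (~3%
#' divergence, a typical congeneric COI gap); within-species mutation rate
#' 0.002 per site; 35% of counts emitted as approximate ("ca"), matching
#' the proportion in the worked karyotype table; one locality holding all
#' four species plus two single-species localities.
#'
#' @param n_species number of species (>= 1; at most 4 when
#'   `n_fixed_diffs > 0`, since every species must carry a distinct base
#'   at each shared diagnostic column).
#' @param base_n integer vector of per-species base haploid counts.
#' @param count_sd integer vector; counts are drawn uniformly from
#'   `[base_n - count_sd, base_n + count_sd]`.
#' @param structures character vector of structure signatures.
#' @param n_samples integer vector of samples per species (all >= 1).
#' @param seq_length barcode length (default 658).
#' @param n_fixed_diffs fixed diagnostic differences per species pair.
#' @param within_species_mutation_rate per-site mutation probability
#'   applied independently to every sample's barcode.
#' @param introgression_pairs list of `c(donor, recipient)` species
#'   indices; the recipient's consensus barcode is replaced by the
#'   donor's before within-species mutation.
#' @param localities list of lists, each with `id` and `species` (integer
#'   vector of species present); every species must appear somewhere.
#' @param approx_fraction probability that a count is emitted as
#'   approximate.
#' @param seed mandatory integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_species = 4L,
    base_n = c(78L, 79L, 74L, 32L),
    count_sd = c(1L, 0L, 1L, 2L),
    structures = c("1L+1M", "1L+0M", "2L+2M", "0L+0M"),
    n_samples = c(8L, 6L, 8L, 8L),
    seq_length = 658L,
    n_fixed_diffs = 20L,
    within_species_mutation_rate = 0.002,
    introgression_pairs = list(),
    localities = list(
      list(id = "L1", species = seq_len(n_species)),
      list(id = "L2", species = 1L),
      list(id = "L3", species = 3L)
    ),
    approx_fraction = 0.35,
    seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  n_species <- as.integer(n_species)
  stopifnot(n_species >= 1L)
  base_n <- rep_len(as.integer(base_n), n_species)
  count_sd <- rep_len(as.integer(count_sd), n_species)
  structures <- rep_len(as.character(structures), n_species)
  n_samples <- rep_len(as.integer(n_samples), n_species)
  if (any(n_samples < 1L)) {
    stop("every species needs n_samples >= 1", call. = FALSE)
  }
  if (any(base_n - count_sd < 1L)) stop("counts must stay >= 1", call. = FALSE)
  stopifnot(within_species_mutation_rate >= 0, within_species_mutation_rate <= 1,
            approx_fraction >= 0, approx_fraction <= 1, seq_length >= 1)
  if (n_fixed_diffs > 0L && n_species > 4L) {
    stop("the shared-diagnostic-column design supports at most 4 species ",
         "when n_fixed_diffs > 0", call. = FALSE)
  }
  if (n_fixed_diffs > seq_length) {
    stop("seq_length too short to host all fixed differences", call. = FALSE)
  }
  parse_structure(structures) # validate
  covered <- sort(unique(unlist(lapply(localities, `[[`, "species"))))
  keep <- lapply(localities, function(l) {
    l$species <- intersect(as.integer(l$species), seq_len(n_species))
    l
  })
  if (!all(seq_len(n_species) %in% covered)) {
    stop("every species must occur at some locality", call. = FALSE)
  }
  structure(list(
    n_species = n_species, base_n = base_n, count_sd = count_sd,
    structures = structures, n_samples = n_samples,
    seq_length = as.integer(seq_length),
    n_fixed_diffs = as.integer(n_fixed_diffs),
    within_species_mutation_rate = within_species_mutation_rate,
    introgression_pairs = introgression_pairs,
    localities = keep, approx_fraction = approx_fraction,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulate a cryptic-species-complex dataset
#'
#' Generates a karyotype table, an aligned barcode FASTA, a locality table
#' and a ground-truth record from a [simulation_config()]. Output is fully
#' determined by the seed: identical configurations produce byte-identical
#' files.
#'
#' Construction: each species gets a consensus barcode equal to a random
#' ancestral sequence except at `n_fixed_diffs` shared diagnostic columns
#' where every species carries a distinct base (so every species pair
#' differs at exactly those columns); introgression then replaces the
#' recipient's consensus with the donor's; each sample's barcode mutates
#' per site at the within-species rate; each sample's haploid count is
#' drawn uniformly from the species interval and flagged approximate with
#' probability `approx_fraction`.
#'
#' @param config a [simulation_config()].
#' @param dir optional output directory; when given, writes
#'   `karyotype.tsv`, `barcodes.fasta`, `localities.tsv`, `truth.json`.
#' @return A list with `karyotype` (data.frame), `alignment`
#'   ([dna_alignment]), `localities` (data.frame), `truth` (list) and,
#'   when `dir` is given, `paths`.
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  K <- config$n_species
  L <- config$seq_length
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, L, replace = TRUE)
  diag_pos <- if (config$n_fixed_diffs > 0L) {
    sort(sample.int(L, config$n_fixed_diffs))
  } else integer()
  consensus <- matrix(rep(ancestor, each = K), nrow = K)
  for (p in diag_pos) {
    ord <- sample(bases) # distinct base per species at this column
    consensus[, p] <- ord[seq_len(K)]
  }
  for (pr in config$introgression_pairs) {
    consensus[pr[[2L]], ] <- consensus[pr[[1L]], ]
  }
  species_of_loc <- lapply(config$localities, `[[`, "species")
  loc_ids <- vapply(config$localities, `[[`, "", "id")

  rows <- list()
  ids <- character()
  seqs <- character()
  for (s in seq_len(K)) {
    ns <- config$n_samples[s]
    sid <- sprintf("SP%d_%02d", s, seq_len(ns))
    counts <- config$base_n[s] +
      sample.int(2L * config$count_sd[s] + 1L, ns, replace = TRUE) -
      config$count_sd[s] - 1L
    appr <- stats::runif(ns) < config$approx_fraction
    eligible <- which(vapply(species_of_loc, function(x) s %in% x, TRUE))
    loc <- loc_ids[eligible[sample.int(length(eligible), ns, replace = TRUE)]]
    seq_mat <- matrix(rep(consensus[s, ], each = ns), nrow = ns)
    if (config$within_species_mutation_rate > 0) {
      hits <- which(matrix(stats::runif(ns * L) <
                             config$within_species_mutation_rate, ns, L),
                    arr.ind = TRUE)
      for (r in seq_len(nrow(hits))) {
        cur <- seq_mat[hits[r, 1L], hits[r, 2L]]
        seq_mat[hits[r, 1L], hits[r, 2L]] <- sample(setdiff(bases, cur), 1L)
      }
    }
    rows[[s]] <- data.frame(
      sample_id = sid, taxon_label = sprintf("species_%d", s),
      n_count = counts, approximate = appr,
      structure = config$structures[s], locality_id = loc,
      reference = "simulated", multivalents_observed = FALSE,
      stringsAsFactors = FALSE
    )
    ids <- c(ids, sid)
    seqs <- c(seqs, apply(seq_mat, 1L, paste, collapse = ""))
  }
  karyo <- do.call(rbind, rows)
  aln <- dna_alignment(ids, seqs)
  loc_df <- data.frame(
    locality_id = loc_ids,
    name = loc_ids,
    lat = 40 + seq_along(loc_ids) - 1,
    lon = 45 + seq_along(loc_ids) - 1,
    stringsAsFactors = FALSE
  )
  truth <- .simulation_truth(config, karyo)
  out <- list(karyotype = karyo, alignment = aln, localities = loc_df,
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      karyotype = file.path(dir, "karyotype.tsv"),
      fasta = file.path(dir, "barcodes.fasta"),
      localities = file.path(dir, "localities.tsv"),
      truth = file.path(dir, "truth.json")
    )
    write_karyotype_table(karyo, paths$karyotype)
    write_alignment(aln, paths$fasta)
    write_locality_table(loc_df, paths$localities)
    write_truth(truth, paths$truth)
    out$paths <- paths
  }
  out
}

# Expected decisions derived from the generating configuration alone
# (never from pipeline output): sympatric pairs are distinct species
# unless introgression erases the mitochondrial contrast (the sympatric
# criterion is blind there); allopatric pairs follow the fixed-difference
# and sublineage rules applied to the configured ranges and structures.
.simulation_truth <- function(config, karyo) {
  K <- config$n_species
  samples <- stats::setNames(karyo$taxon_label, karyo$sample_id)
  if (K < 2L) {
    return(list(samples = samples,
                pairs = data.frame(group_a = character(),
                                   group_b = character(),
                                   decision = character(),
                                   introgression_flag = logical())))
  }
  intro <- vapply(config$introgression_pairs, function(pr) {
    paste(sort(c(pr[[1L]], pr[[2L]])), collapse = "-")
  }, "")
  pairs <- utils::combn(K, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    introgressed <- paste(i, j, sep = "-") %in% intro
    sympatric <- any(vapply(config$localities, function(l) {
      all(c(i, j) %in% l$species)
    }, TRUE))
    barcode_diff <- config$n_fixed_diffs > 0L && !introgressed
    si <- parse_structure(config$structures[i])
    sj <- parse_structure(config$structures[j])
    struct_eq <- si$n_large == sj$n_large && si$n_medium == sj$n_medium
    ri <- c(config$base_n[i] - config$count_sd[i], config$base_n[i] + config$count_sd[i])
    rj <- c(config$base_n[j] - config$count_sd[j], config$base_n[j] + config$count_sd[j])
    gap <- .range_gap(ri, rj)
    flag <- FALSE
    decision <- if (sympatric) {
      if (introgressed) "single_polymorphic_species" else "distinct_species"
    } else if (!struct_eq || gap >= 3L) {
      flag <- !barcode_diff
      "distinct_species"
    } else if (barcode_diff) {
      "conspecific_subspecies"
    } else if (gap == 0L) {
      "synonym"
    } else {
      "unresolved"
    }
    data.frame(group_a = sprintf("species_%d", i),
               group_b = sprintf("species_%d", j),
               decision = decision, introgression_flag = flag,
               stringsAsFactors = FALSE)
  })
  list(samples = samples, pairs = do.call(rbind, rows))
}

#' Worked fixture: the karyotyped-sample table of the ripartii complex
#'
#' Returns paths to the packaged transcription of the published
#' karyotyped-sample table for the Polyommatus ripartii complex of Armenia
#' and NW Iran (62 samples: 48 newly karyotyped plus 14 P. eriwanensis
#' from a prior study), together with a locality table. Counts keep their
#' approximate ("ca") flags; structure signatures follow the described
#' marker-bivalent sets (`1L+1M` for ripartii/emmeli/keleybaricus,
#' `1L+0M` for admetus, `2L+2M` for demavendi, `0L+0M` for eriwanensis,
#' whose marker bivalents are not described). Coordinates are printed
#' type-locality values where available; the remaining localities carry
#' approximate gazetteer coordinates and are only used when a positive
#' merge radius is requested.
#'
#' @return A list with elements `karyotype` and `localities` (file paths).
#' @examples
#' fx <- table1_fixture()
#' nrow(read_karyotype_table(fx$karyotype)) # 62
#' @export
table1_fixture <- function() {
  list(
    karyotype = system.file("extdata", "table1_karyotypes.tsv",
                            package = "karyodelim", mustWork = TRUE),
    localities = system.file("extdata", "table1_localities.tsv",
                             package = "karyodelim", mustWork = TRUE)
  )
}
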