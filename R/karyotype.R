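#' Summarize karyotype observations for one putative taxon
#'
#' Computes the per-group summary used throughout the delimitation rules:
#' the range of exact haploid counts, the range of approximate ("ca")
#' counts, the modal count over all observations (ties broken toward the
#' smaller value, deterministically), the shared structure signature and
#' whether any sample showed multivalents (the chromosomal-heterozygote
#' indicator expected under interspecific hybridization).
#'
#' Exact and approximate counts are summarized separately and never merged:
#' approximate counts arise when no metaphase plate of ideal quality could
#' be found, and carry lower confidence.
#'
#' @param observations a data.frame of karyotype observations for one group
#'   (columns as in [read_karyotype_table()]); must be non-empty.
#' @param group_id identifier for the group.
#' @return An object of class `group_summary`: a list with fields
#'   `group_id`, `n_samples`, `exact_min`, `exact_max`, `approx_min`,
#'   `approx_max` (each `NA` when no count of that kind exists),
#'   `modal_count`, `structure` (signature string or `NA`) and
#'   `any_multivalents`.
#' @examples
#' obs <- data.frame(n_count = c(77L, 78L, 79L), approximate = FALSE,
#'                   structure = "1L+1M", multivalents_observed = FALSE)
#' summarize_group(obs, "emmeli")
#' @export
summarize_group <- function(observations, group_id) {
  if (is.null(observations) || nrow(observations) == 0L) {
    stop("cannot summarize an empty observation list (group ", group_id, ")",
         call. = FALSE)
  }
  n <- observations$n_count
  appr <- observations$approximate
  exact <- n[!appr]
  approx <- n[appr]
  tab <- table(n)
  modal <- min(as.integer(names(tab)[tab == max(tab)]))
  structs <- unique(observations$structure[!is.na(observations$structure)])
  structure_sig <- if (length(structs) == 1L) structs else if (length(structs) == 0L) NA_character_ else {
    warning("group ", group_id, " mixes structure signatures: ",
            paste(structs, collapse = ", "), "; keeping the most frequent")
    st <- table(observations$structure)
    names(st)[which.max(st)]
  }
  structure(list(
    group_id = group_id,
    n_samples = nrow(observations),
    exact_min = if (length(exact)) min(exact) else NA_integer_,
    exact_max = if (length(exact)) max(exact) else NA_integer_,
    approx_min = if (length(approx)) min(approx) else NA_integer_,
    approx_max = if (length(approx)) max(approx) else NA_integer_,
    modal_count = modal,
    structure = structure_sig,
    any_multivalents = any(observations$multivalents_observed %in% TRUE)
  ), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  rng <- if (!is.na(x$exact_min)) {
    if (x$exact_min == x$exact_max) sprintf("n = %d", x$exact_min)
    else sprintf("n = %d-%d", x$exact_min, x$exact_max)
  } else if (!is.na(x$approx_min)) {
    if (x$approx_min == x$approx_max) sprintf("n = ca%d", x$approx_min)
    else sprintf("n = ca%d-ca%d", x$approx_min, x$approx_max)
  } else "n = ?"
  cat(sprintf("group %s: %d sample(s), %s (modal %d), structure %s%s\n",
              x$group_id, x$n_samples, rng, x$modal_count,
              ifelse(is.na(x$structure), "?", x$structure),
              if (x$any_multivalents) ", multivalents observed" else ""))
  invisible(x)
}

#' Summarize all groups in a karyotype table
#'
#' @param observations karyotype data.frame.
#' @param by column used as the group label (default `"taxon_label"`).
#' @return A named list of [summarize_group()] results, in order of first
#'   appearance of each group.
#' @export
summarize_groups <- function(observations, by = "taxon_label") {
  ids <- unique(observations[[by]])
  out <- lapply(ids, function(g) {
    summarize_group(observations[observations[[by]] == g, , drop = FALSE], g)
  })
  names(out) <- ids
  out
}

#' Compare two karyotype group summaries
#'
#' Applies the fixed-difference logic used for allopatric taxa: groups with
#' different marker-bivalent structures are treated as chromosomally
#' distinct regardless of counts; for groups with equal structures the
#' decision depends on the gap between their count ranges. A gap of at
#' least `delta` counts is a "fixed" count difference (species-level
#' evidence), a smaller positive gap a "minor" difference (subspecies
#' level), and overlapping ranges are indistinguishable.
#'
#' Exact count ranges are preferred; a group with only approximate counts
#' is compared on its approximate range and the result is annotated as low
#' confidence.
#'
#' @param a,b `group_summary` objects.
#' @param delta integer; minimum count gap treated as a fixed (species
#'   level) difference. Default 3, chosen so that the subspecific gap of 1
#'   (n = 67-72 vs n = 73-75) and the specific gap of 4 (n = 86 vs n = 90)
#'   fall on opposite sides.
#' @return A list of class `karyo_comparison` with fields `relation` (one
#'   of `"indistinguishable"`, `"minor_count_difference"`,
#'   `"fixed_count_difference"`, `"structure_difference"`), `count_gap`
#'   (distance between nearest range endpoints, 0 when ranges overlap),
#'   `structures_equal` and `low_confidence`.
#' @export
compare_groups <- function(a, b, delta = 3L) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  delta <- as.integer(delta)
  if (is.na(delta) || delta < 1L) stop("`delta` must be a positive integer", call. = FALSE)
  ra <- .usable_range(a)
  rb <- .usable_range(b)
  structures_equal <- .structures_equal(a$structure, b$structure)
  gap <- .range_gap(ra$range, rb$range)
  relation <- if (!structures_equal) {
    "structure_difference"
  } else if (gap >= delta) {
    "fixed_count_difference"
  } else if (gap >= 1L) {
    "minor_count_difference"
  } else {
    "indistinguishable"
  }
  structure(list(
    relation = relation,
    count_gap = gap,
    structures_equal = structures_equal,
    low_confidence = ra$approx_only || rb$approx_only
  ), class = "karyo_comparison")
}

.usable_range <- function(s) {
  if (!is.na(s$exact_min)) {
    list(range = c(s$exact_min, s$exact_max), approx_only = FALSE)
  } else if (!is.na(s$approx_min)) {
    list(range = c(s$approx_min, s$approx_max), approx_only = TRUE)
  } else {
    stop("group ", s$group_id, " has no chromosome counts", call. = FALSE)
  }
}

.range_gap <- function(ra, rb) {
  if (ra[1L] > rb[2L]) ra[1L] - rb[2L]
  else if (rb[1L] > ra[2L]) rb[1L] - ra[2L]
  else 0L
}

.structures_equal <- function(sa, sb) {
  if (is.na(sa) || is.na(sb)) return(TRUE) # unknown structure cannot witness a difference
  pa <- parse_structure(sa)
  pb <- parse_structure(sb)
  pa$n_large == pb$n_large && pa$n_medium == pb$n_medium
}

#' Partition karyotype observations into karyotype classes
#'
#' Groups observations that could plausibly share one karyotype: two
#' observations fall in the same class when their structure signatures are
#' equal and their counts are linked by a chain of differences smaller than
#' `delta` (single linkage on counts within each structure). This is the
#' nuclear-marker classification used by the within-locality association
#' test and by the pipeline's group formation.
#'
#' @param observations karyotype data.frame.
#' @param delta the fixed-difference gap of [compare_groups()].
#' @return A character vector of class labels (e.g. `"1L+1M/77"`, named by
#'   `sample_id`), one per observation; labels are deterministic (smallest
#'   count in the class).
#' @export
karyo_classes <- function(observations, delta = 3L) {
  if (nrow(observations) == 0L) return(stats::setNames(character(), character()))
  struct <- ifelse(is.na(observations$structure), "?", observations$structure)
  out <- rep(NA_character_, nrow(observations))
  for (s in unique(struct)) {
    idx <- which(struct == s)
    counts <- sort(unique(observations$n_count[idx]))
    # chain counts whose consecutive difference < delta
    breaks <- which(diff(counts) >= delta)
    class_of <- integer(length(counts))
    cls <- 1L
    for (i in seq_along(counts)) {
      class_of[i] <- cls
      if (i %in% breaks) cls <- cls + 1L
    }
    names(class_of) <- as.character(counts)
    for (i in idx) {
      k <- class_of[[as.character(observations$n_count[i])]]
      lo <- min(counts[class_of == k])
      out[i] <- sprintf("%s/%d", s, lo)
    }
  }
  stats::setNames(out, observations$sample_id)
}
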