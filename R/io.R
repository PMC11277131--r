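#' Parse and format marker-bivalent structure signatures
#'
#' Karyotype structure is reduced to counts of "large" and "medium-sized"
#' marker bivalents visible at first meiotic metaphase, encoded losslessly
#' as `"<n_large>L+<n_medium>M"` (e.g. `"2L+2M"` for a karyotype with two
#' large and two medium marker bivalents). Relative bivalent sizes are
#' deliberately not modeled numerically: on routine squash preparations
#' bivalent areas are blurred, stain-dependent projections, so only the
#' qualitative marker counts are comparable across samples.
#'
#' @param x for `parse_structure`, a character vector of signature strings;
#'   for `format_structure`, a list/data.frame with `n_large`, `n_medium`.
#' @return `parse_structure`: a data.frame with integer columns `n_large`
#'   and `n_medium`. `format_structure`: a character vector.
#' @examples
#' parse_structure("1L+1M")
#' format_structure(list(n_large = 2L, n_medium = 2L))
#' @export
parse_structure <- function(x) {
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([0-9]+)L\\+([0-9]+)M$", x))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed structure signature: ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected e.g. \"2L+2M\")", call. = FALSE)
  }
  data.frame(
    n_large = vapply(m, function(g) as.integer(g[[2L]]), 1L),
    n_medium = vapply(m, function(g) as.integer(g[[3L]]), 1L)
  )
}

#' @rdname parse_structure
#' @export
format_structure <- function(x) {
  sprintf("%dL+%dM", as.integer(x$n_large), as.integer(x$n_medium))
}

.karyo_required_cols <- c("sample_id", "taxon_label", "n_count", "locality_id",
                          "reference")

#' Read a karyotype observation table
#'
#' Reads a tab-separated table of karyotyped samples. Required columns:
#' `sample_id`, `taxon_label`, `n_count`, `locality_id`, `reference`;
#' optional columns `approximate`, `structure` and `multivalents_observed`
#' default to `FALSE`, `NA` and `FALSE`. The haploid count column accepts
#' `"90"`, `"ca90"` and `"ca 90"`: a `"ca"` prefix marks the count as
#' approximate (metaphase plates of imperfect quality) and is stripped to
#' the integer, never silently merged with exact counts.
#'
#' @param path path to a TSV file with a header row.
#' @return A data.frame with one row per sample, in file order, and columns
#'   `sample_id`, `taxon_label`, `n_count` (integer), `approximate`
#'   (logical), `structure` (signature string or `NA`), `locality_id`,
#'   `reference`, `multivalents_observed` (logical).
#' @export
read_karyotype_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = character())
  missing <- setdiff(.karyo_required_cols, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(.empty_karyotype_table())
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  raw <- trimws(df$n_count)
  ca <- grepl("^ca\\s*", raw, ignore.case = TRUE)
  num <- sub("^ca\\s*", "", raw, ignore.case = TRUE)
  ok <- grepl("^[0-9]+$", num)
  if (any(!ok)) {
    stop("non-integer chromosome count at row(s) ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(unique(raw[!ok]), collapse = ", "), call. = FALSE)
  }
  n_count <- as.integer(num)
  if (any(n_count < 1L)) {
    stop("chromosome counts must be >= 1 (row ",
         paste(which(n_count < 1L), collapse = ", "), ")", call. = FALSE)
  }
  approximate <- ca
  if ("approximate" %in% names(df)) {
    approximate <- approximate | .parse_logical(df$approximate, "approximate")
  }
  structure_sig <- if ("structure" %in% names(df)) {
    s <- trimws(df$structure)
    s[!nzchar(s) | s == "NA"] <- NA_character_
    if (any(!is.na(s))) parse_structure(s[!is.na(s)]) # validate
    s
  } else {
    rep(NA_character_, nrow(df))
  }
  multiv <- if ("multivalents_observed" %in% names(df)) {
    .parse_logical(df$multivalents_observed, "multivalents_observed")
  } else {
    rep(FALSE, nrow(df))
  }
  data.frame(
    sample_id = df$sample_id,
    taxon_label = df$taxon_label,
    n_count = n_count,
    approximate = approximate,
    structure = structure_sig,
    locality_id = df$locality_id,
    reference = df$reference,
    multivalents_observed = multiv,
    stringsAsFactors = FALSE
  )
}

.empty_karyotype_table <- function() {
  data.frame(sample_id = character(), taxon_label = character(),
             n_count = integer(), approximate = logical(),
             structure = character(), locality_id = character(),
             reference = character(), multivalents_observed = logical(),
             stringsAsFactors = FALSE)
}

.parse_logical <- function(x, col) {
  x <- toupper(trimws(x))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO", "", "NA")] <- FALSE
  if (anyNA(out)) {
    stop("cannot parse logical column `", col, "`: ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a karyotype observation table
#'
#' Inverse of [read_karyotype_table()]: the round trip preserves every
#' field, including the approximate flag (written as its own column, with a
#' plain integer count).
#'
#' @param df a karyotype data.frame as returned by [read_karyotype_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_karyotype_table <- function(df, path) {
  out <- df[, c("sample_id", "taxon_label", "n_count", "approximate",
                "structure", "locality_id", "reference",
                "multivalents_observed")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write a locality table
#'
#' Locality tables are TSV with columns `locality_id`, `name`, `lat`, `lon`
#' (decimal degrees, `"."` decimal separator). Latitude must lie in
#' \[-90, 90\] and longitude in \[-180, 180\].
#'
#' @param path path to a TSV file.
#' @return A data.frame with columns `locality_id`, `name`, `lat`, `lon`.
#' @export
read_locality_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(c("locality_id", "name", "lat", "lon"), names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lat <- .parse_coord(df$lat, "lat")
  lon <- .parse_coord(df$lon, "lon")
  if (any(lat < -90 | lat > 90)) stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(lon < -180 | lon > 180)) stop("longitude outside [-180, 180]", call. = FALSE)
  if (anyDuplicated(df$locality_id)) {
    stop("duplicate locality_id: ",
         paste(unique(df$locality_id[duplicated(df$locality_id)]), collapse = ", "),
         call. = FALSE)
  }
  data.frame(locality_id = df$locality_id, name = df$name,
             lat = lat, lon = lon, stringsAsFactors = FALSE)
}

.parse_coord <- function(x, col) {
  x <- trimws(x)
  ok <- grepl("^-?[0-9]+(\\.[0-9]+)?$", x)
  if (any(!ok)) {
    stop("cannot parse `", col, "` value(s): ",
         paste(unique(x[!ok]), collapse = ", "),
         " (decimal degrees with '.' separator required)", call. = FALSE)
  }
  as.numeric(x)
}

#' @rdname read_locality_table
#' @param df a locality data.frame.
#' @export
write_locality_table <- function(df, path) {
  out <- df[, c("locality_id", "name", "lat", "lon")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a phylogenetic tree in newick format
#'
#' Thin validated wrappers around [ape::write.tree()] / [ape::read.tree()].
#' Writing requires uniquely named leaves; a round trip preserves topology
#' and branch lengths to within 1e-9.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param path file path.
#' @return `write_newick`: `path` invisibly; `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  labs <- tree$tip.label
  if (any(is.na(labs)) || any(!nzchar(labs))) {
    stop("tree has unnamed leaves", call. = FALSE)
  }
  if (anyDuplicated(labs)) {
    stop("duplicate leaf names: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ape::read.tree(path)
}

#' Write / read simulation ground truth
#'
#' Ground truth for a synthetic dataset: the true species of every sample
#' and the expected pairwise decision for every species pair, serialized as
#' JSON.
#'
#' @param truth a list with elements `samples` (named character vector or
#'   list, sample_id -> species id) and `pairs` (data.frame with columns
#'   `group_a`, `group_b`, `decision`, `introgression_flag`).
#' @param path file path.
#' @return `write_truth`: `path` invisibly; `read_truth`: the truth list.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(samples = as.list(truth$samples), pairs = truth$pairs),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$samples <- unlist(x$samples)
  x
}
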