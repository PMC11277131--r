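#' Aligned nucleotide sequences
#'
#' A `dna_alignment` holds equal-length, uppercase nucleotide sequences as a
#' character matrix (one row per sequence, one column per alignment
#' position). Positions are 1-based throughout the package, so a diagnostic
#' site reported at position 411 refers to column 411 of this matrix.
#'
#' @param ids character vector of unique, non-empty sequence identifiers.
#' @param sequences character vector of sequences (one string each), all of
#'   the same length. Lowercase is normalized to uppercase and `U` to `T`.
#'
#' @return An object of class `dna_alignment` with elements `ids`,
#'   `matrix` (character, `length(ids)` x `length`) and `length`.
#' @export
dna_alignment <- function(ids, sequences) {
  ids <- as.character(ids)
  sequences <- toupper(as.character(sequences))
  sequences <- chartr("U", "T", sequences)
  if (length(ids) != length(sequences)) {
    stop("`ids` and `sequences` must have the same length", call. = FALSE)
  }
  if (length(ids) == 0L) stop("alignment must contain at least one sequence", call. = FALSE)
  if (anyDuplicated(ids)) {
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(ids))) stop("sequence ids must be non-empty", call. = FALSE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    off <- ids[lens != stats::median(lens)]
    stop("sequences are not all the same length; offending ids: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  allowed <- c("A", "C", "G", "T", "N", "-",
               "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "?")
  mat <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
                nrow = length(ids), byrow = TRUE)
  bad <- setdiff(unique(as.vector(mat)), allowed)
  if (length(bad)) {
    stop("unexpected characters in alignment: ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  rownames(mat) <- ids
  structure(list(ids = ids, matrix = mat, length = lens[[1L]]),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("dna_alignment: %d sequences x %d positions\n",
              length(x$ids), x$length))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA file of pre-aligned nucleotide
#' sequences and enforces the alignment invariants: equal lengths, unique
#' ids, uppercase states with `U` mapped to `T`.
#'
#' @param path path to a FASTA file.
#' @return A [dna_alignment].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dna_alignment(ids, as.character(set))
}

#' Write an alignment to FASTA
#'
#' @param aln a [dna_alignment].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "dna_alignment"))
  seqs <- apply(aln$matrix, 1L, paste, collapse = "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Extract sequences for a set of samples
#'
#' @param aln a [dna_alignment].
#' @param ids sample ids; all must be present in the alignment.
#' @return A `dna_alignment` restricted to `ids`, in the given order.
#' @export
subset_alignment <- function(aln, ids) {
  missing <- setdiff(ids, aln$ids)
  if (length(missing)) {
    stop("ids not in alignment: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  dna_alignment(ids, apply(aln$matrix[ids, , drop = FALSE], 1L, paste, collapse = ""))
}
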