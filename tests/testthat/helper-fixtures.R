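# Small builders shared across test files; everything is generated in code.

make_obs <- function(counts, approximate = FALSE, structure = "1L+1M",
                     multivalents = FALSE, ids = NULL) {
  n <- length(counts)
  data.frame(
    sample_id = if (is.null(ids)) sprintf("s%02d", seq_len(n)) else ids,
    taxon_label = rep_len("t", n),
    n_count = as.integer(counts),
    approximate = rep_len(approximate, n),
    structure = rep_len(structure, n),
    locality_id = rep_len("L", n),
    reference = rep_len("test", n),
    multivalents_observed = rep_len(multivalents, n),
    stringsAsFactors = FALSE
  )
}

make_aln <- function(seqs, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("q%02d", seq_along(seqs))
  dna_alignment(ids, seqs)
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

random_sequences <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, "")
}

# Independent column-scan oracle for diagnostic sites
brute_diagnostic <- function(aln, ga, gb) {
  unamb <- c("A", "C", "G", "T")
  out <- integer()
  for (p in seq_len(aln$length)) {
    sa <- intersect(unique(aln$matrix[ga, p]), unamb)
    sb <- intersect(unique(aln$matrix[gb, p]), unamb)
    if (length(sa) && length(sb) && !length(intersect(sa, sb))) {
      out <- c(out, p)
    }
  }
  out
}

# Four-point-condition oracle for the unrooted 4-taxon topology: the true
# cherry pairing minimizes d(i,j) + d(k,l) over the three pairings.
best_quartet <- function(d) {
  stopifnot(nrow(d) == 4L)
  sums <- c(d[1, 2] + d[3, 4], d[1, 3] + d[2, 4], d[1, 4] + d[2, 3])
  list(c("12|34", "13|24", "14|23")[which.min(sums)], sums)[[1L]]
}

# Which split does a 4-taxon unrooted tree imply (by tip labels t1..t4)?
tree_quartet <- function(tree, labs) {
  for (pair in list(c(1, 2), c(1, 3), c(1, 4))) {
    other <- setdiff(1:4, pair)
    if (ape::is.monophyletic(ape::unroot(tree), labs[pair]) ||
        ape::is.monophyletic(ape::unroot(tree), labs[other])) {
      return(paste0(pair[1], pair[2], "|", other[1], other[2]))
    }
  }
  NA_character_
}
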