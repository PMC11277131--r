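.UNAMBIG <- c("A", "C", "G", "T")

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites over comparable sites, where a site is
#' comparable when both sequences carry an unambiguous `A`/`C`/`G`/`T`
#' (pairwise deletion of gaps, `N` and IUPAC ambiguity codes). This is the
#' raw distance conventionally reported for COI barcodes.
#'
#' @param seq_a,seq_b equal-length nucleotide strings (or single-character
#'   vectors).
#' @return A proportion in \[0, 1\], or `NA_real_` when the pair shares no
#'   comparable site (an undefined distance, deliberately distinct from 0).
#' @examples
#' p_distance("ACGT", "ACGA") # 0.25
#' p_distance("ACGN", "ACGA") # 0 over 3 comparable sites
#' @export
p_distance <- function(seq_a, seq_b) {
  a <- .to_chars(seq_a)
  b <- .to_chars(seq_b)
  if (length(a) != length(b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  comp <- a %in% .UNAMBIG & b %in% .UNAMBIG
  n <- sum(comp)
  if (n == 0L) return(NA_real_)
  sum(a[comp] != b[comp]) / n
}

.to_chars <- function(x) {
  if (length(x) == 1L) strsplit(toupper(x), "", fixed = TRUE)[[1L]] else toupper(x)
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln a [dna_alignment] with at least two sequences.
#' @return A symmetric numeric matrix with zero diagonal, dimnames set to
#'   the sequence ids; entries are `NA` where a pair shares no comparable
#'   site.
#' @export
distance_matrix <- function(aln) {
  stopifnot(inherits(aln, "dna_alignment"))
  n <- length(aln$ids)
  if (n < 2L) stop("distance matrix requires at least 2 sequences", call. = FALSE)
  m <- aln$matrix
  unamb <- matrix(m %in% .UNAMBIG, nrow = n)
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- unamb[i, ] & unamb[j, ]
      nc <- sum(comp)
      d[i, j] <- d[j, i] <-
        if (nc == 0L) NA_real_ else sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  d
}

#' Minimum between-group p-distance
#'
#' The minimum pairwise distance between members of two groups — the
#' quantity conventionally reported as the minimum COI p-distance between
#' taxa.
#'
#' @param dm distance matrix from [distance_matrix()].
#' @param group_a,group_b character vectors of sequence ids.
#' @return A single proportion (`NA` if every cross pair is undefined).
#' @export
min_group_distance <- function(dm, group_a, group_b) {
  missing <- setdiff(c(group_a, group_b), rownames(dm))
  if (length(missing)) {
    stop("ids not in distance matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  block <- dm[group_a, group_b, drop = FALSE]
  if (all(is.na(block))) NA_real_ else min(block, na.rm = TRUE)
}

#' Cluster sequences into haplogroups by distance threshold
#'
#' Single-linkage clustering cut at `theta`: two samples share a haplogroup
#' when they are connected by a chain of pairwise distances `<= theta`.
#' This is the distance-based stand-in for reading mitochondrial clusters
#' off a phylogenetic tree. Group ids `H1, H2, ...` are assigned by order
#' of each cluster's first member in the input, so the partition is
#' invariant to input order up to that deterministic relabeling.
#'
#' @param dm distance matrix; no `NA` among clustered samples.
#' @param theta distance threshold in \[0, 1\]. Default 0.02, a
#'   conventional 2% barcode-gap value (a formalization — not a quantity
#'   estimated from data).
#' @return A named character vector, `sample_id -> haplogroup id`, with
#'   attribute `threshold_used`.
#' @export
cluster_haplogroups <- function(dm, theta = 0.02) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) ||
      theta < 0 || theta > 1) {
    stop("`theta` must be a proportion in [0, 1]", call. = FALSE)
  }
  ids <- rownames(dm)
  n <- length(ids)
  if (anyNA(dm)) {
    stop("distance matrix contains undefined entries; remove those samples first",
         call. = FALSE)
  }
  if (n == 1L) {
    out <- stats::setNames("H1", ids)
    attr(out, "threshold_used") <- theta
    return(out)
  }
  # connected components of the graph {d <= theta}, via union-find
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (dm[i, j] <= theta) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  first <- !duplicated(roots)
  labels <- stats::setNames(paste0("H", seq_len(sum(first))), roots[first])
  out <- stats::setNames(unname(labels[as.character(roots)]), ids)
  attr(out, "threshold_used") <- theta
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration yielding an unrooted tree.
#' Deterministic behavior is pinned down in two places where
#' implementations differ: when two joins minimize the Q-criterion equally,
#' the pair whose (sorted) leaf labels are lexicographically smallest is
#' joined; and negative branch lengths are clamped to zero with the
#' deficit moved to the sister branch, preserving the path length between
#' the joined nodes.
#'
#' @param dm symmetric distance matrix with at least 3 taxa and no `NA`.
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  ids <- rownames(dm)
  n <- length(ids)
  if (n < 3L) {
    stop("neighbor joining requires >= 3 taxa; the topology of ", n,
         " taxa is trivial", call. = FALSE)
  }
  if (anyNA(dm)) stop("distance matrix contains undefined entries", call. = FALSE)
  d <- unname(dm)
  # active nodes: newick fragment + smallest contained leaf label (tie-break key)
  frag <- ids
  key <- ids
  repeat {
    m <- nrow(d)
    if (m == 3L) break
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    ck <- apply(cand, 1L, function(ij) {
      k <- sort(c(key[ij[1L]], key[ij[2L]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(ck)[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- d[i, j] - vi
    lens <- .clamp_pair(vi, vj)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], lens[1L], frag[j], lens[2L])
    newkey <- min(key[i], key[j])
    dn <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]), c(dn[keep], 0))
    d <- d2
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
  }
  # final three-node star: closed-form three-point branch lengths
  va <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  vb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  vc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  v <- .clamp_star(c(va, vb, vc))
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1L], v[1L], frag[2L], v[2L], frag[3L], v[3L])
  ape::read.tree(text = nwk)
}

.clamp_pair <- function(vi, vj) {
  if (vi < 0) { vj <- vj + vi; vi <- 0 }
  if (vj < 0) { vi <- vi + vj; vj <- 0 }
  c(max(vi, 0), max(vj, 0))
}

.clamp_star <- function(v) {
  # move each deficit onto the longest remaining branch
  for (i in seq_along(v)) {
    if (v[i] < 0) {
      j <- which.max(replace(v, i, -Inf))
      v[j] <- v[j] + v[i]
      v[i] <- 0
    }
  }
  pmax(v, 0)
}

#' Diagnostic fixed sites between two groups
#'
#' Scans alignment columns for positions where the sets of unambiguous
#' nucleotide states observed in two groups are disjoint — fixed diagnostic
#' substitutions in the barcoding sense (e.g. a T/A difference at position
#' 411). By default a column is eligible when each group shows at least one
#' unambiguous state there; gaps, `N` and ambiguity codes are ignored
#' rather than disqualifying the column. With `strict = TRUE` a column is
#' disqualified if any member of either group carries a non-ACGT state.
#'
#' @param aln a [dna_alignment].
#' @param group_a,group_b disjoint, non-empty sets of sequence ids.
#' @param strict logical; see above.
#' @return A data.frame with columns `position` (1-based, ascending),
#'   `states_a` and `states_b` (sorted concatenations such as `"T"` or
#'   `"A/G"`).
#' @export
diagnostic_sites <- function(aln, group_a, group_b, strict = FALSE) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("groups must be non-empty", call. = FALSE)
  }
  overlap <- intersect(group_a, group_b)
  if (length(overlap)) {
    stop("groups overlap: ", paste(overlap, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(c(group_a, group_b), aln$ids)
  if (length(missing)) {
    stop("ids not in alignment: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  ma <- aln$matrix[group_a, , drop = FALSE]
  mb <- aln$matrix[group_b, , drop = FALSE]
  pos <- integer()
  sa_out <- character()
  sb_out <- character()
  for (p in seq_len(aln$length)) {
    ca <- ma[, p]
    cb <- mb[, p]
    sa <- unique(ca[ca %in% .UNAMBIG])
    sb <- unique(cb[cb %in% .UNAMBIG])
    if (strict && (any(!ca %in% .UNAMBIG) || any(!cb %in% .UNAMBIG))) next
    if (length(sa) == 0L || length(sb) == 0L) next
    if (length(intersect(sa, sb)) == 0L) {
      pos <- c(pos, p)
      sa_out <- c(sa_out, paste(sort(sa), collapse = "/"))
      sb_out <- c(sb_out, paste(sort(sb), collapse = "/"))
    }
  }
  data.frame(position = pos, states_a = sa_out, states_b = sb_out,
             stringsAsFactors = FALSE)
}
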