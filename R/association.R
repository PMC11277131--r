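#' Detect sympatry between groups
#'
#' Builds the locality -> groups map and the pairwise co-occurrence matrix.
#' Localities whose great-circle (haversine) distance is at most
#' `radius_km` are merged into one site (single linkage) before
#' co-occurrence is computed; with the default `radius_km = 0` the map is a
#' pure group-by on `locality_id`, which matches data recorded against
#' named collecting localities.
#'
#' @param records data.frame with columns `sample_id`, `group_id`,
#'   `locality_id` (one row per sample).
#' @param localities optional locality table ([read_locality_table()]);
#'   required when `radius_km > 0`.
#' @param radius_km merge radius in kilometres, `>= 0`.
#' @return An object of class `sympatry_map`: a list with `site_of`
#'   (locality_id -> site id), `site_groups` (site id -> character vector
#'   of group ids present) and `cooccurrence` (logical group x group
#'   matrix; `TRUE` when some site contains both groups).
#' @export
detect_sympatry <- function(records, localities = NULL, radius_km = 0) {
  stopifnot(all(c("sample_id", "group_id", "locality_id") %in% names(records)))
  if (!is.numeric(radius_km) || radius_km < 0) {
    stop("`radius_km` must be >= 0", call. = FALSE)
  }
  locs <- unique(records$locality_id)
  if (!is.null(localities)) {
    unknown <- setdiff(locs, localities$locality_id)
    if (length(unknown)) {
      bad <- records$sample_id[records$locality_id %in% unknown]
      stop("unknown locality_id for sample(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (radius_km > 0) {
    if (is.null(localities)) {
      stop("`localities` with coordinates are required when radius_km > 0",
           call. = FALSE)
    }
    coord <- localities[match(locs, localities$locality_id), c("lon", "lat")]
    km <- geosphere::distm(as.matrix(coord), fun = geosphere::distHaversine) / 1000
    parent <- seq_along(locs)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (i in seq_along(locs)) {
      for (j in seq_along(locs)) {
        if (i < j && km[i, j] <= radius_km) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    roots <- vapply(seq_along(locs), find, 1L)
  } else {
    roots <- seq_along(locs)
  }
  first <- !duplicated(roots)
  site_ids <- stats::setNames(paste0("site_", seq_len(sum(first))), roots[first])
  site_of <- stats::setNames(unname(site_ids[as.character(roots)]), locs)
  sites <- unique(unname(site_of))
  site_groups <- lapply(sites, function(s) {
    sort(unique(records$group_id[site_of[records$locality_id] == s]))
  })
  names(site_groups) <- sites
  groups <- sort(unique(records$group_id))
  co <- matrix(FALSE, length(groups), length(groups),
               dimnames = list(groups, groups))
  for (gs in site_groups) {
    co[gs, gs] <- TRUE
  }
  structure(list(site_of = site_of, site_groups = site_groups,
                 cooccurrence = co),
            class = "sympatry_map")
}

#' Are two groups sympatric?
#'
#' @param map a [detect_sympatry()] result.
#' @param a,b group ids.
#' @return `TRUE` when some site contains both groups.
#' @export
is_sympatric <- function(map, a, b) {
  stopifnot(inherits(map, "sympatry_map"))
  if (!a %in% rownames(map$cooccurrence) || !b %in% rownames(map$cooccurrence)) {
    return(FALSE)
  }
  isTRUE(map$cooccurrence[a, b])
}

#' G-statistic of a contingency table
#'
#' Likelihood-ratio statistic `2 * sum O log(O/E)` with expected counts
#' from the margins; empty cells contribute zero. Chosen over Pearson's
#' X^2 for robustness on the sparse tables typical of small collecting
#' samples.
#'
#' @param tab an integer matrix of counts.
#' @return Non-negative scalar.
#' @export
g_statistic <- function(tab) {
  tab <- as.matrix(tab)
  n <- sum(tab)
  if (n == 0L) return(0)
  e <- outer(rowSums(tab), colSums(tab)) / n
  nz <- tab > 0
  2 * sum(tab[nz] * log(tab[nz] / e[nz]))
}

#' Permutation test of karyotype-haplogroup association
#'
#' Tests, within one locality, whether nuclear (karyotype class) and
#' mitochondrial (haplogroup) markers are associated. Under intraspecific
#' polymorphism the two unlinked marker systems should be in linkage
#' equilibrium (all combinations formed at random); reproductively isolated
#' species instead show stable species-specific combinations that mimic
#' linkage disequilibrium. The null distribution of the G-statistic is
#' obtained by permuting haplogroup labels. When the number of distinct
#' label permutations (a multinomial coefficient) is at most
#' `exact_limit`, the null is enumerated exactly over all tables with the
#' observed margins (multivariate hypergeometric weights); otherwise `m`
#' random permutations are drawn and the add-one estimator
#' `p = (b + 1) / (m + 1)` is used, where `b` counts permutations with a
#' statistic at least as large as the observed one.
#'
#' @param karyo_class character vector of karyotype class labels, one per
#'   sample.
#' @param haplogroup character vector of haplogroup labels, same length.
#' @param n_permutations number of sampled permutations (`>= 99`) when
#'   exact enumeration is not used.
#' @param seed integer seed for the sampled-permutation path (mandatory
#'   for reproducibility; ignored by the exact path).
#' @param exact_limit enumerate exactly when the number of distinct label
#'   permutations is at most this (default 10000).
#' @param locality_id optional label carried into the result.
#' @return A list of class `association_result`: `locality_id`, `table`,
#'   `statistic`, `p_value`, `n_permutations` (0 for exact enumeration),
#'   `method` (`"exact"` or `"permutation"`), `seed`, and `one_to_one`
#'   (`TRUE` when each karyotype class maps to exactly one haplogroup and
#'   vice versa — the stable-combination criterion, which is deliberately
#'   separate from mere significance).
#' @examples
#' association_test(rep(c("K1", "K2"), each = 5),
#'                  rep(c("H1", "H2"), each = 5), seed = 1)
#' @export
association_test <- function(karyo_class, haplogroup, n_permutations = 9999,
                             seed = NULL, exact_limit = 10000,
                             locality_id = NA_character_) {
  if (length(karyo_class) != length(haplogroup)) {
    stop("label vectors must have equal length", call. = FALSE)
  }
  if (length(karyo_class) < 2L) stop("need at least 2 samples", call. = FALSE)
  tab <- table(karyo_class, haplogroup)
  one_to_one <- all(rowSums(tab > 0) == 1L) && all(colSums(tab > 0) == 1L)
  if (nrow(tab) == 1L && ncol(tab) == 1L) {
    warning("degenerate table: a single karyotype class and haplogroup")
    return(structure(list(locality_id = locality_id, table = unclass(tab),
                          statistic = 0, p_value = 1, n_permutations = 0L,
                          method = "degenerate", seed = seed,
                          one_to_one = TRUE),
                     class = "association_result"))
  }
  if (n_permutations < 99) stop("`n_permutations` must be >= 99", call. = FALSE)
  g_obs <- g_statistic(tab)
  n <- length(haplogroup)
  cs <- colSums(tab)
  n_distinct <- exp(lfactorial(n) - sum(lfactorial(cs)))
  if (n_distinct <= exact_limit) {
    p <- .exact_assoc_p(tab, g_obs)
    res <- list(p_value = p, n_permutations = 0L, method = "exact")
  } else {
    if (!is.null(seed)) set.seed(seed)
    b <- 0L
    for (k in seq_len(n_permutations)) {
      gk <- g_statistic(table(karyo_class, sample(haplogroup)))
      if (gk >= g_obs - 1e-12) b <- b + 1L
    }
    res <- list(p_value = (b + 1) / (n_permutations + 1),
                n_permutations = as.integer(n_permutations),
                method = "permutation")
  }
  structure(list(locality_id = locality_id, table = unclass(tab),
                 statistic = g_obs, p_value = res$p_value,
                 n_permutations = res$n_permutations, method = res$method,
                 seed = seed, one_to_one = one_to_one),
            class = "association_result")
}

# Exact null: enumerate every table with the observed margins; each table's
# probability under label permutation is the multivariate hypergeometric
# mass. p = total probability of tables with G >= observed.
.exact_assoc_p <- function(tab, g_obs) {
  rs <- rowSums(tab)
  cs <- colSums(tab)
  n <- sum(tab)
  lognorm <- sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n)
  p <- 0
  cells <- matrix(0L, nrow(tab), ncol(tab))
  recurse <- function(i, j, row_left, col_left) {
    if (i > nrow(tab)) {
      g <- g_statistic(cells)
      if (g >= g_obs - 1e-12) {
        p <<- p + exp(lognorm - sum(lfactorial(cells)))
      }
      return(invisible())
    }
    if (j == ncol(tab)) {
      v <- row_left
      if (v > col_left[j]) return(invisible())
      cells[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i + 1L, 1L, rs[i + 1L][1L], cl)
      return(invisible())
    }
    for (v in 0:min(row_left, col_left[j])) {
      cells[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i, j + 1L, row_left - v, cl)
    }
    invisible()
  }
  recurse(1L, 1L, rs[1L], cs)
  min(p, 1)
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("association test (%s): G = %.4g, p = %.4g, one-to-one: %s\n",
              x$method, x$statistic, x$p_value, x$one_to_one))
  invisible(x)
}

#' Screen karyotype observations for chromosomal heterozygotes
#'
#' Interspecific hybrids heterozygous for chromosomal fusions/fissions are
#' expected to show tri- and multivalents at first meiotic metaphase, so
#' the presence of multivalents among co-occurring samples argues against
#' reproductive isolation.
#'
#' @param observations karyotype data.frame (may be empty).
#' @return `TRUE` iff any observation has `multivalents_observed = TRUE`;
#'   an empty list returns `FALSE` with a warning.
#' @export
heterozygote_screen <- function(observations) {
  if (is.null(observations) || nrow(observations) == 0L) {
    warning("no karyotype observations supplied; heterozygote screen is vacuous")
    return(FALSE)
  }
  any(observations$multivalents_observed %in% TRUE)
}
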