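test_that("p-distance counts mismatches over comparable sites only", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("ACGN", "ACGA"), 0) # N excluded, 3 comparable sites
  expect_equal(p_distance("AC-T", "ACGT"), 0) # gap excluded
  expect_true(is.na(p_distance("NNNN", "ACGT"))) # undefined, not zero
  expect_error(p_distance("ACG", "ACGT"), "equal length")
})

test_that("p-distance is a symmetric proportion, zero iff identical", {
  set.seed(1)
  for (i in 1:30) {
    s <- random_sequences(2, 40, alphabet = c("A", "C", "G", "T", "N", "-"))
    d1 <- p_distance(s[1], s[2])
    d2 <- p_distance(s[2], s[1])
    expect_equal(d1, d2)
    if (!is.na(d1)) expect_true(d1 >= 0 && d1 <= 1)
  }
  expect_equal(p_distance("ANGT", "A-GT"), 0)
})

test_that("distance matrix is symmetric with zero diagonal and matches
           pairwise computation and an independent raw-distance oracle", {
  set.seed(2)
  aln <- make_aln(random_sequences(6, 120))
  dm <- distance_matrix(aln)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 6))
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(dm[i, j],
                 p_distance(paste(aln$matrix[i, ], collapse = ""),
                            paste(aln$matrix[j, ], collapse = "")))
  }
  # independent oracle: ape's raw pairwise-deletion distance
  bin <- ape::as.DNAbin(strsplit(apply(aln$matrix, 1, paste, collapse = ""), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(unname(dm), unname(ref[rownames(dm), rownames(dm)]),
               tolerance = 1e-12)

  ident <- make_aln(rep("ACGTACGT", 2))
  expect_equal(unname(distance_matrix(ident)), matrix(0, 2, 2))
})

test_that("haplogroup clustering is single linkage at the threshold", {
  seq_a <- paste(rep("A", 100), collapse = "")
  seq_b <- paste(c(rep("A", 90), rep("C", 10)), collapse = "") # d = 0.10
  aln <- make_aln(c(seq_a, seq_a, seq_b, seq_b), ids = c("a1", "a2", "b1", "b2"))
  dm <- distance_matrix(aln)
  hap <- cluster_haplogroups(dm, theta = 0.02)
  expect_equal(length(unique(hap)), 2L)
  expect_equal(hap[["a1"]], hap[["a2"]])
  expect_false(hap[["a1"]] == hap[["b1"]])
  expect_equal(attr(hap, "threshold_used"), 0.02)

  expect_equal(length(unique(cluster_haplogroups(dm, theta = 1))), 1L)
  expect_equal(length(unique(cluster_haplogroups(distance_matrix(
    make_aln(rep(seq_a, 3))), theta = 0.02))), 1L)
  expect_error(cluster_haplogroups(dm, theta = 1.5), "proportion")
})

test_that("haplogroup partition is invariant to input order", {
  set.seed(3)
  base <- random_sequences(1, 100)
  seqs <- c(base, base, chartr("A", "C", base), chartr("A", "C", base))
  ids <- c("w", "x", "y", "z")
  dm1 <- distance_matrix(make_aln(seqs, ids))
  perm <- c(3, 1, 4, 2)
  dm2 <- distance_matrix(make_aln(seqs[perm], ids[perm]))
  h1 <- cluster_haplogroups(dm1, 0.02)
  h2 <- cluster_haplogroups(dm2, 0.02)
  for (i in ids) for (j in ids) {
    expect_equal(h1[[i]] == h1[[j]], h2[[i]] == h2[[j]])
  }
})

test_that("neighbor joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  # three-point formulas: vA = (dAB + dAC - dBC)/2 etc.
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(lens[["A"]], 0.1)
  expect_equal(lens[["B"]], 0.2)
  expect_equal(lens[["C"]], 0.3)
  expect_error(neighbor_joining(d[1:2, 1:2]), "3 taxa")
})

test_that("neighbor joining recovers additive quartets and cherry pairs", {
  # additive distances on ((A,B),(C,D)) with internal branch 0.2
  labs <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  pend <- c(A = 0.1, B = 0.15, C = 0.12, D = 0.2)
  for (i in 1:3) for (j in (i + 1):4) {
    thru <- if (i <= 2 && j >= 3) 0.2 else 0
    d[i, j] <- d[j, i] <- pend[i] + pend[j] + thru
  }
  expect_equal(best_quartet(d), "12|34") # four-point oracle
  tr <- neighbor_joining(d)
  expect_equal(tree_quartet(tr, labs), "12|34")
  expect_true(all(tr$edge.length >= 0))
  # total path length A..B reproduced on the additive input
  expect_equal(sum(ape::cophenetic.phylo(tr)["A", "B"]), d["A", "B"],
               tolerance = 1e-9)

  # ultrametric with two clear pairs: pairs must be cherries
  du <- matrix(0.5, 4, 4, dimnames = list(labs, labs))
  diag(du) <- 0
  du["A", "B"] <- du["B", "A"] <- 0.02
  du["C", "D"] <- du["D", "C"] <- 0.04
  expect_equal(tree_quartet(neighbor_joining(du), labs), "12|34")
})

test_that("neighbor joining matches ape on random additive trees", {
  set.seed(4)
  for (i in 1:10) {
    n <- sample(5:9, 1)
    ref <- ape::rtree(n, rooted = FALSE)
    ref$edge.length <- stats::runif(length(ref$edge.length), 0.05, 0.5)
    d <- ape::cophenetic.phylo(ref)
    mine <- neighbor_joining(d)
    theirs <- ape::nj(d)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs))[[1]], 0)
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref))[[1]], 0)
    expect_true(all(mine$edge.length >= 0))
  }
})

test_that("diagnostic sites are fixed disjoint-state columns", {
  aln <- make_aln(c("ACGT", "ACGT", "ACGA", "ACGA"),
                  ids = c("a1", "a2", "b1", "b2"))
  d <- diagnostic_sites(aln, c("a1", "a2"), c("b1", "b2"))
  expect_equal(d$position, 4L)
  expect_equal(d$states_a, "T")
  expect_equal(d$states_b, "A")

  expect_equal(nrow(diagnostic_sites(aln, "a1", "a2")), 0L) # identical
  # overlapping state sets at the only varying column
  aln2 <- make_aln(c("ACGT", "ACGT", "ACGA"), ids = c("x", "y", "z"))
  expect_equal(nrow(diagnostic_sites(aln2, "x", c("y", "z"))), 0L)
  expect_error(diagnostic_sites(aln, c("a1", "b1"), c("b1", "b2")), "overlap")
})

test_that("missing data handling: lenient ignores N, strict disqualifies", {
  aln <- make_aln(c("ANT", "AAT", "AGC", "AGC"), ids = c("a1", "a2", "b1", "b2"))
  len <- diagnostic_sites(aln, c("a1", "a2"), c("b1", "b2"))
  expect_equal(len$position, c(2L, 3L)) # column 2: {A} vs {G} after ignoring N
  strict <- diagnostic_sites(aln, c("a1", "a2"), c("b1", "b2"), strict = TRUE)
  expect_equal(strict$position, 3L)
})

test_that("diagnostic site detection agrees with a brute-force column scan
           and is symmetric under group swap", {
  set.seed(5)
  for (i in 1:20) {
    seqs <- random_sequences(6, 60, alphabet = c("A", "C", "G", "T", "N", "-"))
    aln <- make_aln(seqs)
    ga <- aln$ids[1:3]
    gb <- aln$ids[4:6]
    mine <- diagnostic_sites(aln, ga, gb)
    expect_equal(mine$position, brute_diagnostic(aln, ga, gb))
    swapped <- diagnostic_sites(aln, gb, ga)
    expect_equal(swapped$position, mine$position)
    expect_equal(swapped$states_a, mine$states_b)
    expect_equal(swapped$states_b, mine$states_a)
  }
})

test_that("two clades separated by m fixed mutations yield exactly m sites", {
  set.seed(6)
  base <- random_sequences(1, 200)
  m <- 7L
  pos <- sort(sample.int(200, m))
  chars <- strsplit(base, "")[[1]]
  other <- chars
  flip <- c(A = "G", C = "T", G = "A", T = "C")
  other[pos] <- flip[other[pos]]
  aln <- make_aln(c(rep(base, 3), rep(paste(other, collapse = ""), 3)))
  d <- diagnostic_sites(aln, aln$ids[1:3], aln$ids[4:6])
  expect_equal(nrow(d), m)
  expect_equal(d$position, pos)
})

test_that("minimum between-group distance picks the closest cross pair", {
  # hand enumeration: cross distances are 1, 0.75, 0.75, 1 -> min 0.75
  aln <- make_aln(c("AAAA", "AAAT", "TTTT", "TTTA"))
  dm <- distance_matrix(aln)
  expect_equal(min_group_distance(dm, aln$ids[1:2], aln$ids[3:4]), 0.75)
  expect_error(min_group_distance(dm, "nope", aln$ids[3:4]), "nope")
})
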