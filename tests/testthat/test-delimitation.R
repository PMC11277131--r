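ev <- function(sympatric, relation, p = NA_real_, one = NA, het = FALSE,
               bd = NA, nsites = 0L) {
  list(sympatric = sympatric, karyo_relation = relation, association_p = p,
       one_to_one = one, heterozygotes = het, barcode_differentiated = bd,
       n_diagnostic_sites = nsites)
}

test_that("the rule engine reproduces the four published scenarios", {
  # sympatric clusters with stable combinations and no heterozygotes
  gnishik <- decide(ev(TRUE, "structure_difference", p = 0.001, one = TRUE,
                       bd = TRUE, nsites = 3L))
  expect_equal(gnishik$decision, "distinct_species")
  expect_equal(gnishik$rule_fired, "R1")

  # allopatric, fixed count gap, shared barcodes: introgression
  emmeli_vs_paralcestis <- decide(ev(FALSE, "fixed_count_difference", bd = FALSE))
  expect_equal(emmeli_vs_paralcestis$decision, "distinct_species")
  expect_equal(emmeli_vs_paralcestis$rule_fired, "R3")
  expect_true(emmeli_vs_paralcestis$introgression_flag)

  # allopatric, minor count gap, differentiated sublineages: subspecies
  belovi_vs_demavendi <- decide(ev(FALSE, "minor_count_difference", bd = TRUE,
                                   nsites = 2L))
  expect_equal(belovi_vs_demavendi$decision, "conspecific_subspecies")
  expect_equal(belovi_vs_demavendi$rule_fired, "R4")

  # allopatric, identical karyotype, identical barcodes: synonym
  yeranyani_vs_anatoliensis <- decide(ev(FALSE, "indistinguishable", bd = FALSE))
  expect_equal(yeranyani_vs_anatoliensis$decision, "synonym")
  expect_equal(yeranyani_vs_anatoliensis$rule_fired, "R5")
})

test_that("sympatric evidence without isolation signals polymorphism", {
  loose <- decide(ev(TRUE, "minor_count_difference", p = 0.4, one = FALSE))
  expect_equal(loose$decision, "single_polymorphic_species")
  expect_equal(loose$rule_fired, "R2")
  hybrid <- decide(ev(TRUE, "structure_difference", p = 0.001, one = TRUE,
                      het = TRUE))
  expect_equal(hybrid$decision, "single_polymorphic_species")
})

test_that("unclassifiable evidence is unresolved, not forced", {
  odd <- decide(ev(FALSE, "minor_count_difference", bd = FALSE))
  expect_equal(odd$decision, "unresolved")
  expect_equal(odd$rule_fired, "R6")
  karyonly <- decide(ev(FALSE, "fixed_count_difference", bd = NA))
  expect_equal(karyonly$decision, "distinct_species")
  expect_false(karyonly$introgression_flag) # unknown barcodes never claim introgression
})

test_that("decide is pure and rejects inconsistent evidence", {
  e <- ev(TRUE, "structure_difference", p = 0.01, one = TRUE, bd = TRUE)
  expect_identical(decide(e), decide(e))
  expect_error(decide(ev(TRUE, "indistinguishable", p = NA_real_)),
               "inconsistent")
  # exactly one rule fires for any evidence combination
  set.seed(8)
  rels <- c("indistinguishable", "minor_count_difference",
            "fixed_count_difference", "structure_difference")
  for (i in 1:60) {
    sym <- sample(c(TRUE, FALSE), 1)
    e <- ev(sym, sample(rels, 1),
            p = if (sym) stats::runif(1) else NA_real_,
            one = sample(c(TRUE, FALSE), 1),
            het = sample(c(TRUE, FALSE), 1),
            bd = sample(c(TRUE, FALSE, NA), 1))
    v <- decide(e)
    expect_true(v$rule_fired %in% paste0("R", 1:6))
    expect_true(v$decision %in% c("distinct_species", "conspecific_subspecies",
                                  "synonym", "single_polymorphic_species",
                                  "unresolved"))
  }
})

test_that("barcode differentiation is fixed-site OR distance exceedance", {
  aln <- make_aln(c("ACGT", "ACGT", "ACGA", "ACGA"),
                  ids = c("a1", "a2", "b1", "b2"))
  dm <- distance_matrix(aln)
  bd <- barcode_differentiation(aln, c("a1", "a2"), c("b1", "b2"), dm)
  expect_true(bd$differentiated)
  expect_equal(bd$n_diagnostic_sites, 1L)

  same <- make_aln(rep("ACGTACGT", 4), ids = c("a1", "a2", "b1", "b2"))
  bd2 <- barcode_differentiation(same, c("a1", "a2"), c("b1", "b2"),
                                 distance_matrix(same))
  expect_false(bd2$differentiated)
  expect_equal(bd2$n_diagnostic_sites, 0L)

  # polymorphic groups: no fixed site, but min distance 0.10 > theta 0.02.
  # b1 differs from the a-haplotype at columns 1-10, b2 at columns 11-20,
  # so every varying column still shares a state across the groups.
  base <- paste(rep("A", 100), collapse = "")
  b1 <- paste0(strrep("T", 10), substr(base, 11, 100))
  b2 <- paste0(substr(base, 1, 10), strrep("T", 10), substr(base, 21, 100))
  aln3 <- make_aln(c(base, base, b1, b2), ids = c("a1", "a2", "b1", "b2"))
  dm3 <- distance_matrix(aln3)
  bd3 <- barcode_differentiation(aln3, c("a1", "a2"), c("b1", "b2"), dm3,
                                 theta = 0.02)
  expect_equal(bd3$n_diagnostic_sites, 0L)
  expect_true(bd3$differentiated)
  expect_gt(bd3$min_distance, 0.02)
})

test_that("the pipeline recovers a simulated three-species truth", {
  cfg <- simulation_config(
    n_species = 3, base_n = c(90L, 78L, 74L), count_sd = c(0L, 1L, 1L),
    structures = c("1L+1M", "1L+1M", "2L+2M"), n_samples = c(6L, 6L, 6L),
    localities = list(list(id = "L1", species = c(2L, 3L)),
                      list(id = "L2", species = 1L)),
    seed = 21)
  sim <- simulate_dataset(cfg, dir = tempfile())
  res <- run_pipeline(sim$paths$karyotype, sim$paths$fasta,
                      sim$paths$localities,
                      run_config(n_permutations = 499, seed = 21))
  evl <- evaluate_against_truth(res, sim$truth)
  expect_equal(evl$accuracy, 1)
  expect_equal(evl$precision, 1)
  expect_equal(evl$recall, 1)
})

test_that("pipeline edge cases: single group and disjoint inputs", {
  cfg <- simulation_config(n_species = 1, base_n = 70L, count_sd = 1L,
                           structures = "1L+1M", n_samples = 4L,
                           localities = list(list(id = "L1", species = 1L)),
                           seed = 3)
  sim <- simulate_dataset(cfg, dir = tempfile())
  res <- run_pipeline(sim$paths$karyotype, sim$paths$fasta,
                      sim$paths$localities, run_config(seed = 3))
  expect_equal(nrow(res$verdicts), 0L)
  expect_equal(nrow(res$groups), 1L)

  karyo <- make_obs(c(70, 71), ids = c("k1", "k2"))
  aln <- make_aln(c("ACGT", "ACGA"), ids = c("q1", "q2"))
  expect_error(run_pipeline(karyo, aln), "joint samples")
})

test_that("reports embed the configuration and are reproducible", {
  cfg <- simulation_config(seed = 5)
  sim <- simulate_dataset(cfg, dir = tempfile())
  rc <- run_config(n_permutations = 199, seed = 5)
  d1 <- tempfile(); d2 <- tempfile()
  write_delimitation_report(
    run_pipeline(sim$paths$karyotype, sim$paths$fasta, sim$paths$localities, rc), d1)
  write_delimitation_report(
    run_pipeline(sim$paths$karyotype, sim$paths$fasta, sim$paths$localities, rc), d2)
  files <- c("groups.tsv", "verdicts.tsv", "associations.tsv", "tree.nwk")
  expect_true(all(file.exists(file.path(d1, files))))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  hdr <- readLines(file.path(d1, "verdicts.tsv"), n = 2)
  expect_match(hdr[2], "seed=5")
  expect_match(hdr[2], "n_permutations=199")
})
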