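test_that("identical seeds give byte-identical outputs", {
  cfg <- simulation_config(seed = 101)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_dataset(cfg, dir = d1)
  simulate_dataset(cfg, dir = d2)
  for (f in c("karyotype.tsv", "barcodes.fasta", "localities.tsv",
              "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes at least the barcodes
  d3 <- tempfile()
  simulate_dataset(simulation_config(seed = 102), dir = d3)
  expect_false(identical(readLines(file.path(d1, "barcodes.fasta")),
                         readLines(file.path(d3, "barcodes.fasta"))))
})

test_that("noise-free species pairs differ at exactly the configured sites", {
  cfg <- simulation_config(
    n_species = 2, base_n = c(90L, 78L), count_sd = c(0L, 0L),
    structures = c("1L+1M", "1L+1M"), n_samples = c(3L, 3L),
    n_fixed_diffs = 5L, within_species_mutation_rate = 0,
    localities = list(list(id = "L1", species = 1L),
                      list(id = "L2", species = 2L)),
    seed = 13)
  sim <- simulate_dataset(cfg)
  ga <- sim$karyotype$sample_id[sim$karyotype$taxon_label == "species_1"]
  gb <- sim$karyotype$sample_id[sim$karyotype$taxon_label == "species_2"]
  d <- diagnostic_sites(sim$alignment, ga, gb)
  expect_equal(nrow(d), 5L)
  dm <- distance_matrix(sim$alignment)
  expect_equal(min_group_distance(dm, ga, gb), 5 / 658)
  # within species, sequences are identical at rate 0
  expect_equal(max(dm[ga, ga]), 0)
})

test_that("haploid counts stay inside the configured interval across seeds", {
  for (seed in 1:20) {
    cfg <- simulation_config(seed = seed)
    sim <- simulate_dataset(cfg)
    for (s in seq_len(cfg$n_species)) {
      counts <- sim$karyotype$n_count[
        sim$karyotype$taxon_label == sprintf("species_%d", s)]
      expect_true(all(counts >= cfg$base_n[s] - cfg$count_sd[s]))
      expect_true(all(counts <= cfg$base_n[s] + cfg$count_sd[s]))
    }
  }
})

test_that("a fully sympatric layout is seen as such by sympatry detection", {
  cfg <- simulation_config(
    localities = list(list(id = "gnishik_like", species = 1:4)), seed = 17)
  sim <- simulate_dataset(cfg)
  recs <- data.frame(sample_id = sim$karyotype$sample_id,
                     group_id = sim$karyotype$taxon_label,
                     locality_id = sim$karyotype$locality_id,
                     stringsAsFactors = FALSE)
  sym <- detect_sympatry(recs, sim$localities, radius_km = 0)
  expect_equal(length(sym$site_groups[[1]]), 4L)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_samples = c(0L, 4L, 4L, 4L), seed = 1),
               "n_samples")
  expect_error(simulation_config(seq_length = 10L, n_fixed_diffs = 20L,
                                 seed = 1), "too short")
  expect_error(simulation_config(seed = 1, n_species = 5L,
                                 base_n = rep(50L, 5), count_sd = 0L,
                                 structures = "1L+1M", n_samples = 2L,
                                 localities = list(list(id = "L", species = 1:5))),
               "at most 4")
  expect_error(simulation_config(), "seed")
})

test_that("introgressed recipients carry the donor haplotype", {
  cfg <- simulation_config(
    n_species = 2, base_n = c(90L, 78L), count_sd = c(0L, 0L),
    structures = c("1L+1M", "1L+1M"), n_samples = c(3L, 3L),
    within_species_mutation_rate = 0,
    introgression_pairs = list(c(1L, 2L)),
    localities = list(list(id = "L1", species = 1L),
                      list(id = "L2", species = 2L)),
    seed = 19)
  sim <- simulate_dataset(cfg)
  ga <- sim$karyotype$sample_id[sim$karyotype$taxon_label == "species_1"]
  gb <- sim$karyotype$sample_id[sim$karyotype$taxon_label == "species_2"]
  dm <- distance_matrix(sim$alignment)
  expect_equal(min_group_distance(dm, ga, gb), 0)
  expect_equal(nrow(diagnostic_sites(sim$alignment, ga, gb)), 0L)
  expect_equal(sim$truth$pairs$decision, "distinct_species")
  expect_true(sim$truth$pairs$introgression_flag)
})

test_that("truth round-trips through JSON", {
  cfg <- simulation_config(seed = 23)
  d <- tempfile()
  sim <- simulate_dataset(cfg, dir = d)
  back <- read_truth(file.path(d, "truth.json"))
  expect_equal(back$samples, sim$truth$samples)
  expect_equal(back$pairs$decision, sim$truth$pairs$decision)
})
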