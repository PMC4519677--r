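test_that("simulation honors cardinality, labels, and planted registry", {
  sim <- simulate_species_set(sim_params(7, 3, 800, kappa = 2,
                                         d_inter = 0.02, d_intra = 0.001,
                                         seed = 1))
  expect_length(sim$sequences, 21)
  expect_identical(length(unique(sim$species_map$species)), 7L)
  expect_true(all(nchar(sim$sequences) == 800))
  expect_identical(nrow(sim$registry), 21L)   # 3 per species
  expect_identical(ape::Ntip(sim$tree), 21L)
})

test_that("zero intraspecific divergence gives identical genotypes", {
  sim <- simulate_species_set(sim_params(n_species = 3, n_per_species = 3,
                                         seq_length = 300, d_intra = 0,
                                         seed = 2))
  for (s in unique(sim$species_map$species)) {
    ids <- sim$species_map$sample_id[sim$species_map$species == s]
    expect_identical(length(unique(sim$sequences[ids])), 1L, label = s)
  }
})

test_that("identical parameters and seed give byte-identical output", {
  p <- sim_params(n_species = 4, n_per_species = 2, seq_length = 250,
                  seed = 99)
  s1 <- simulate_species_set(p)
  s2 <- simulate_species_set(p)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$registry, s2$registry)
  s3 <- simulate_species_set(sim_params(n_species = 4, n_per_species = 2,
                                        seq_length = 250, seed = 100))
  expect_false(identical(s1$sequences, s3$sequences))
})

test_that("realized transition:transversion ratio converges to kappa", {
  # with kappa = 2 a substituted site is a transition with p = 1/2
  sim <- simulate_species_set(sim_params(n_species = 2, n_per_species = 1,
                                         seq_length = 20000, kappa = 2,
                                         d_inter = 0.1, d_intra = 0,
                                         n_planted_diagnostic = 0,
                                         seed = 3))
  pc <- pair_counts(sim$sequences[[1]], sim$sequences[[2]])
  ts <- pc$P * pc$n; tv <- pc$Q * pc$n
  chisq <- stats::chisq.test(c(ts, tv), p = c(0.5, 0.5))
  expect_gt(chisq$p.value, 0.001)
})

test_that("planting guards reject impossible demands", {
  expect_error(simulate_species_set(
    sim_params(n_species = 7, n_per_species = 1, seq_length = 10,
               n_planted_diagnostic = 3, seed = 1)), "planted")
  expect_error(sim_params(seed = 1, d_inter = 0.01, d_intra = 0.02))
  expect_error(sim_params(n_species = 2))   # missing seed
})

test_that("simulated quality matches the generator-side truth under QC", {
  seqc <- random_dna(400, seed = 81)
  # dip-free profile: truth is the full high-quality plateau
  sq <- simulate_quality(seqc, quality_profile(dip_rate = 0), seed = 5)
  expect_identical(sq$truth$status, "accepted")
  res <- run_qc(sq$qseq)
  expect_identical(res$trimmed_range, sq$truth$retained)
  r <- sq$truth$retained
  expect_true(all(sq$qseq$phred[(r[1] + 1):r[2]][1:10] > 20))

  # ends already above threshold: nothing to trim
  sq <- simulate_quality(seqc, quality_profile(end_phred = 30), seed = 6)
  expect_identical(sq$truth$retained, c(0L, 400L))
  expect_identical(run_qc(sq$qseq)$trimmed_range, c(0L, 400L))

  # random dip-laden profiles: QC output equals the truth registry
  for (i in 1:25) {
    sq <- simulate_quality(seqc, quality_profile(dip_rate = 0.05),
                           seed = 100 + i)
    res <- run_qc(sq$qseq)
    expect_identical(res$trimmed_range, sq$truth$retained)
    expect_identical(res$status, sq$truth$status)
    if (res$status == "accepted") {
      expect_equal(res$n_fraction, sq$truth$n_fraction, tolerance = 1e-12)
    }
  }
})

test_that("hybrids copy the maternal template verbatim", {
  sim <- simulate_species_set(sim_params(n_species = 2, n_per_species = 1,
                                         seq_length = 200, seed = 7))
  h <- make_hybrid(sim$sequences[["sp1_1"]], "ate")
  expect_identical(names(h), "ate")
  expect_identical(unname(h), unname(sim$sequences[["sp1_1"]]))
})
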