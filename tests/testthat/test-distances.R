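test_that("pair counts classify substitutions and drop gap/N columns", {
  pc <- pair_counts("ACGT", "ACGT")
  expect_equal(c(pc$P, pc$Q, pc$n), c(0, 0, 4))

  pc <- pair_counts("AAAA", "GAAA")         # A<->G transition
  expect_equal(c(pc$P, pc$Q, pc$n), c(0.25, 0, 4))

  # hand count over 6 columns: N and gap columns excluded, T/A transversion
  pc <- pair_counts("ACGTN-", "ACGAAC")
  expect_identical(pc$n, 4L)
  expect_equal(pc$P, 0)
  expect_equal(pc$Q, 0.25)

  pc <- pair_counts("NN--", "ACGT")
  expect_identical(pc$n, 0L)
  expect_true(is.na(pc$P))
})

test_that("K2P formula matches its closed form and flags saturation", {
  expect_equal(k2p(list(P = 0, Q = 0)), 0)
  expect_equal(k2p(list(P = 0.1, Q = 0.05)),
               -0.5 * log(0.75 * sqrt(0.9)), tolerance = 1e-12)
  expect_lt(abs(k2p(list(P = 0.1, Q = 0.05)) - 0.1702), 1e-4)
  expect_warning(res <- k2p(list(P = 0.5, Q = 0)), "saturation")
  expect_true(is.na(res))
})

test_that("distance_matrix composes per-pair counts and the K2P formula", {
  set.seed(31)
  base <- strsplit(random_dna(40), "")[[1]]
  rows <- vapply(1:4, function(i) {
    v <- base
    idx <- sample(40, 5)
    v[idx] <- sample(c("A", "C", "G", "T"), 5, replace = TRUE)
    paste(v, collapse = "")
  }, "")
  names(rows) <- paste0("t", 1:4)
  aln <- labeled_alignment(rows, setNames(rep("spX", 4), names(rows)))
  dm <- distance_matrix(aln)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(dm$d[i, j],
                 k2p(pair_counts(rows[[i]], rows[[j]])), tolerance = 1e-12)
    expect_equal(dm$d[i, j], dm$d[j, i])
  }
  expect_true(all(diag(dm$d) == 0))
  expect_true(all(dm$sites_used[upper.tri(dm$sites_used)] == 40L))
})

test_that("K2P agrees with an independent reference implementation", {
  set.seed(32)
  sim <- simulate_species_set(sim_params(n_species = 4, n_per_species = 2,
                                         seq_length = 400, d_inter = 0.05,
                                         d_intra = 0.005,
                                         n_planted_diagnostic = 0, seed = 32))
  aln <- labeled_alignment(sim$sequences, sim$species_map)
  dm <- distance_matrix(aln)
  bin <- ape::as.DNAbin(lapply(aln$rows, function(s) {
    strsplit(tolower(s), "")[[1]]
  }))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = TRUE))
  expect_equal(dm$d[rownames(ref), colnames(ref)], ref, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("row permutation permutes labels but not distances", {
  set.seed(33)
  base <- strsplit(random_dna(60), "")[[1]]
  rows <- setNames(vapply(1:5, function(i) {
    v <- base
    idx <- sample(60, 6)
    v[idx] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    paste(v, collapse = "")
  }, ""), paste0("t", 1:5))
  sp <- setNames(rep("s", 5), names(rows))
  dm1 <- distance_matrix(labeled_alignment(rows, sp))
  perm <- c(4, 2, 5, 1, 3)
  dm2 <- distance_matrix(labeled_alignment(rows[perm], sp))
  expect_equal(dm2$d[names(rows), names(rows)], dm1$d, tolerance = 1e-15)
})

test_that("the K2P correction never falls below the p-distance", {
  set.seed(34)
  for (rep in 1:1000) {
    n <- 50
    P <- 0; Q <- 0
    while (TRUE) {
      nd <- sample(0:15, 1)
      ts <- sample(0:nd, 1)
      P <- ts / n; Q <- (nd - ts) / n
      if (1 - 2 * P - Q > 0 && 1 - 2 * Q > 0) break
    }
    counts <- list(P = P, Q = Q, n = n)
    expect_true(k2p(counts) >= p_distance(counts) - 1e-12)
  }
})

test_that("mean K2P estimate recovers the true divergence", {
  ests <- vapply(1:100, function(i) {
    sim <- simulate_species_set(sim_params(n_species = 2, n_per_species = 1,
                                           seq_length = 800, d_inter = 0.02,
                                           d_intra = 0,
                                           n_planted_diagnostic = 0,
                                           seed = 5000 + i))
    k2p(pair_counts(sim$sequences[[1]], sim$sequences[[2]]))
  }, 0)
  se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 0.02), 3 * se)
})
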