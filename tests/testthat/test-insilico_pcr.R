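test_that("exact binding sites equal a naive substring scan", {
  set.seed(71)
  tmpl <- random_dna(200)
  primer <- substr(tmpl, 11, 30)
  sites <- find_binding_sites(primer, tmpl)
  plus <- sites[sites$strand == "plus", ]
  expect_identical(plus$start, 10L)
  expect_identical(plus$mismatches, 0L)
  expect_identical(plus$start, oracle_exact_sites(primer, tmpl))

  expect_identical(nrow(find_binding_sites(strrep("ACGT", 5), strrep("T", 100))),
                   0L)
  for (rep in 1:20) {
    t2 <- random_dna(150)
    st <- sample(1:120, 1)
    p2 <- substr(t2, st, st + 19)
    got <- find_binding_sites(p2, t2)
    expect_setequal(got$start[got$strand == "plus"],
                    oracle_exact_sites(p2, t2))
  }
})

test_that("mismatch tolerance honors the 3' clamp rule", {
  set.seed(72)
  for (rep in 1:30) {
    tmpl <- random_dna(120)
    st <- sample(1:90, 1)
    p <- strsplit(substr(tmpl, st, st + 19), "")[[1]]
    pos <- sample(1:20, 1)
    flip <- c(A = "C", C = "A", G = "T", T = "G")
    p[pos] <- flip[[p[pos]]]
    primer <- paste(p, collapse = "")
    got <- find_binding_sites(primer, tmpl, pcr_params(max_mismatch = 1))
    oracle <- oracle_mismatch_sites(primer, tmpl, 1, 3)
    expect_setequal(got$start[got$strand == "plus"], oracle)
    if (pos > 17) {
      expect_false((st - 1L) %in% got$start[got$strand == "plus"])
    } else {
      expect_true((st - 1L) %in% got$start[got$strand == "plus"])
    }
  }
})

test_that("template N never matches", {
  tmpl <- paste0(strrep("A", 10), "N", "CGT", strrep("A", 10))
  sites <- find_binding_sites(strrep("A", 10), tmpl)
  plus <- sites[sites$strand == "plus", ]
  # only the two clean poly-A runs; every window crossing the N is out
  expect_setequal(plus$start, c(0L, 14L))
  # even with a mismatch budget the N stays a mismatch
  sites <- find_binding_sites(strrep("A", 10), tmpl,
                              pcr_params(max_mismatch = 0))
  expect_false(any(sites$start %in% 1:13 & sites$strand == "plus"))
})

test_that("amplicon lengths follow the inclusive coordinate arithmetic", {
  set.seed(73)
  tmpl <- random_dna(100)
  fwd <- substr(tmpl, 11, 30)                       # plus site 10..29
  rev <- reverse_complement(substr(tmpl, 71, 90))   # minus site 70..89
  preds <- predict_amplicons(fwd, rev, tmpl)
  expect_identical(nrow(preds), 1L)
  expect_identical(preds$product_length, 80L)       # 89 - 10 + 1
  expect_identical(preds$fwd_start, 10L)
  expect_identical(preds$rev_end, 89L)
})

test_that("predictions are strand-symmetric", {
  set.seed(74)
  for (rep in 1:10) {
    tmpl <- random_dna(300)
    a <- sample(1:100, 1); b <- sample(180:270, 1)
    fwd <- substr(tmpl, a, a + 19)
    rev <- reverse_complement(substr(tmpl, b, b + 19))
    direct <- predict_amplicons(fwd, rev, tmpl)
    mirrored <- predict_amplicons(rev, fwd, revcomp(tmpl))
    expect_identical(direct$product_length, mirrored$product_length)
  }
})

test_that("specificity matrix is diagonal for planted-site markers", {
  sim <- simulate_species_set(sim_params(n_species = 4, n_per_species = 2,
                                         seq_length = 500, seed = 75))
  aln <- labeled_alignment(sim$sequences, sim$species_map)
  markers <- lapply(unique(aln$species_of), function(s) {
    design_primer_pairs(aln, s, design_constraints(product_min = 100,
                                                   product_max = 450))[[1]]
  })
  smat <- specificity_matrix(markers, sim$sequences, aln$species_of)
  expect_true(all(smat$specific))
  for (i in seq_along(markers)) {
    tgt <- smat$species_of[smat$samples] == markers[[i]]$target_species
    expect_true(all(lengths(smat$cells[i, smat$samples[tgt]]) == 1L))
    expect_true(all(lengths(smat$cells[i, smat$samples[!tgt]]) == 0L))
    expect_true(all(unlist(smat$cells[i, ]) == markers[[i]]$expected_size))
  }
})

test_that("universal primers band in every species", {
  sim <- simulate_species_set(sim_params(n_species = 3, n_per_species = 1,
                                         seq_length = 400, d_inter = 0.01,
                                         n_planted_diagnostic = 0,
                                         seed = 76))
  # conserved flanks: prepend/append invariant anchors to every template
  left <- random_dna(25, seed = 761); right <- random_dna(25, seed = 762)
  templates <- vapply(sim$sequences, function(s) {
    paste0(left, s, right)
  }, "")
  uni <- marker_pair(
    primer_candidate("uniF", "F", substr(left, 1, 20)),
    primer_candidate("uniR", "R", reverse_complement(substr(right, 6, 25))),
    "any", 450)
  smat <- specificity_matrix(list(uni), templates, sim$species_map)
  expect_true(all(lengths(smat$cells) == 1L))
})

test_that("maternal-parent inference follows chloroplast marker presence", {
  sim <- simulate_species_set(sim_params(n_species = 3, n_per_species = 2,
                                         seq_length = 500, seed = 77))
  aln <- labeled_alignment(sim$sequences, sim$species_map)
  mk <- lapply(c("sp1", "sp2"), function(s) {
    design_primer_pairs(aln, s, design_constraints(product_min = 100,
                                                   product_max = 450))[[1]]
  })
  hyb_a <- make_hybrid(sim$sequences[["sp1_1"]], "hybA")
  res <- infer_maternal_parent(hyb_a, mk)
  expect_identical(res$maternal, "sp1")
  expect_identical(res$status, "resolved")

  hyb_b <- make_hybrid(sim$sequences[["sp2_2"]], "hybB")
  expect_identical(infer_maternal_parent(hyb_b, mk)$maternal, "sp2")

  # a template from an unrelated species amplifies neither marker
  stranger <- make_hybrid(sim$sequences[["sp3_1"]], "hybC")
  res <- infer_maternal_parent(stranger, mk)
  expect_identical(res$status, "inconclusive")
  expect_true(is.na(res$maternal))

  # both markers firing is also inconclusive, with a warning
  chimera <- paste0(sim$sequences[["sp1_1"]], sim$sequences[["sp2_1"]])
  expect_warning(res <- infer_maternal_parent(chimera, mk), "multiple")
  expect_identical(res$status, "inconclusive")
})
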