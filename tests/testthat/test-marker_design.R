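test_that("diagnostic sites are found by exhaustive column logic", {
  aln <- toy_two_species_alignment()       # sp1 ACGT / sp2 ACTT
  s1 <- find_diagnostic_sites(aln, "sp1")
  expect_identical(s1$column, 2L)
  expect_identical(s1$target_state, "G")
  expect_identical(s1$background_states, "T")
  s2 <- find_diagnostic_sites(aln, "sp2")
  expect_identical(s2$column, 2L)
  expect_identical(s2$target_state, "T")

  # identical species share every state: nothing is diagnostic
  rows <- c(x1 = "ACGT", y1 = "ACGT")
  aln2 <- labeled_alignment(rows, c(x1 = "sp1", y1 = "sp2"))
  expect_identical(nrow(find_diagnostic_sites(aln2, "sp1")), 0L)

  # intraspecific polymorphism disqualifies a column
  rows <- c(x1 = "ACGT", x2 = "ACTT", y1 = "ACAT")
  aln3 <- labeled_alignment(rows, c(x1 = "sp1", x2 = "sp1", y1 = "sp2"))
  expect_false(2L %in% find_diagnostic_sites(aln3, "sp1")$column)
})

test_that("diagnostic sites ignore row order and duplicated sequences", {
  sim <- simulate_species_set(sim_params(n_species = 3, n_per_species = 2,
                                         seq_length = 200, seed = 61))
  aln <- labeled_alignment(sim$sequences, sim$species_map)
  base <- find_diagnostic_sites(aln, "sp2")
  perm <- rev(seq_along(aln$rows))
  aln_p <- labeled_alignment(aln$rows[perm], aln$species_of)
  expect_identical(find_diagnostic_sites(aln_p, "sp2"), base)
  rows_d <- c(aln$rows, dup = unname(aln$rows[["sp2_1"]]))
  sp_d <- c(aln$species_of, dup = "sp2")
  expect_identical(find_diagnostic_sites(labeled_alignment(rows_d, sp_d),
                                         "sp2")$column, base$column)
})

test_that("planted diagnostic sites are all recovered", {
  sim <- simulate_species_set(sim_params(seed = 62))
  aln <- labeled_alignment(sim$sequences, sim$species_map)
  for (s in unique(sim$registry$species)) {
    found <- find_diagnostic_sites(aln, s)
    planted <- sim$registry[sim$registry$species == s, ]
    expect_true(all(planted$column %in% found$column), label = s)
    hit <- found[match(planted$column, found$column), ]
    expect_identical(hit$target_state, planted$base)
  }
})

test_that("calibrated nearest-neighbor Tm reproduces the reference panel", {
  panel <- list(
    c("GTATATGAATGTGAATCGGTATTC", 58.3), c("TTGACTCCTTACTGCGGAAT", 61.7),
    c("GCTTCGGAATGATTTTCC", 60.1),       c("CGCCTTAGCCAACGATT", 61.9),
    c("CCATTTCCGTTTGTTCAAAC", 62.2),     c("GGTAAGATTTCCATTTCTTCATC", 59.8),
    c("CATTTACGATCAACATCCTTTA", 58.6),   c("GAAGAATTTTGGCGTACACTTA", 60.2),
    c("ATACAAGATGCTCCCTCTTTG", 60.2),    c("TTAGCCAATGATCCAATCATT", 61.2),
    c("CGATCAACATCCTTTGGG", 62.1),       c("GCCGGCTTACTAATAGGGTT", 61.3),
    c("TTCTTGTTCCTATATAATATTCATA", 53.2), c("GAGAAAGATTTCTGTATATGCGT", 58.5))
  for (p in panel) {
    expect_equal(melting_temperature(p[[1]]), as.numeric(p[[2]]),
                 tolerance = 0.5 / as.numeric(p[[2]]), label = p[[1]])
  }
})

test_that("Tm is duplex-symmetric and responds to G/C extension", {
  set.seed(63)
  for (rep in 1:10) {
    s <- random_dna(sample(15:25, 1))
    expect_equal(melting_temperature(s),
                 melting_temperature(reverse_complement(s)),
                 tolerance = 1e-9)
  }
  s <- random_dna(18, seed = 64)
  expect_gte(melting_temperature(paste0("G", s)), melting_temperature(s))
  expect_gte(melting_temperature(paste0(s, "C")), melting_temperature(s))
  expect_error(melting_temperature("ACGTNACGTACGT"), "ambiguous|short")
})

test_that("designed pairs are anchored, sized as planted, and validated", {
  # two species, diagnostic SNPs planted ~300 bp apart
  set.seed(65)
  base <- random_dna(600)
  v <- strsplit(base, "")[[1]]
  v2 <- v
  flip <- c(A = "C", C = "A", G = "T", T = "G")
  v2[150] <- flip[[v[150]]]
  v2[450] <- flip[[v[450]]]
  rows <- c(a1 = paste(v, collapse = ""), a2 = paste(v, collapse = ""),
            b1 = paste(v2, collapse = ""), b2 = paste(v2, collapse = ""))
  aln <- labeled_alignment(rows, c(a1 = "spA", a2 = "spA",
                                   b1 = "spB", b2 = "spB"))
  pairs <- design_primer_pairs(aln, "spB",
                               design_constraints(product_min = 200,
                                                  product_max = 400))
  expect_gt(length(pairs), 0)
  best <- pairs[[1]]
  expect_true(best$forward$anchored || best$reverse$anchored)
  expect_true(abs(best$expected_size - 300) <= 60)  # primer placement slack
  expect_true(nchar(best$forward$sequence) %in% 17:27)
  expect_true(nchar(best$reverse$sequence) %in% 17:27)
  # by construction: exactly one product on targets, none on background
  for (id in names(rows)) {
    n_prod <- nrow(predict_amplicons(best$forward$sequence,
                                     best$reverse$sequence, rows[[id]]))
    expect_identical(n_prod, if (grepl("^b", id)) 1L else 0L, label = id)
  }
})

test_that("design reports a failure tally when no pair is feasible", {
  rows <- c(x1 = "ACGTACGTACGTACGTACGTACGT",
            y1 = "ACGTACGTACGTACGTACGTACGT")
  aln <- labeled_alignment(rows, c(x1 = "sp1", y1 = "sp2"))
  pairs <- design_primer_pairs(aln, "sp1")
  expect_length(pairs, 0)
  expect_identical(attr(pairs, "failure_tally")[["no_diagnostic_site"]], 1L)
})

test_that("3'-interaction screening flags dimers and spares benign pairs", {
  p <- "ACGTACGTACGTACGTAC"
  sc <- screen_interactions(c(p = p, rc = reverse_complement(p)))
  cross <- sc$pairs[sc$pairs$primer_a == "p" & sc$pairs$primer_b == "rc", ]
  expect_true(cross$flagged)
  expect_identical(cross$run, nchar(p))

  sc <- screen_interactions(c(a = strrep("A", 20), c = strrep("C", 20)))
  expect_false(any(sc$pairs$flagged))

  # constructed 5-base 3' complement
  a <- paste0(strrep("A", 15), "GCGCG")
  b <- paste0(strrep("A", 15), "CGCGC")
  sc <- screen_interactions(c(a = a, b = b), threshold = 5)
  expect_true(sc$pairs$flagged[sc$pairs$primer_a == "a" &
                                 sc$pairs$primer_b == "b"])

  # hairpin: 4-base stem, 3-base loop
  hp <- paste0(strrep("T", 8), "GGGC", "AAA", "GCCC", strrep("T", 4))
  sc <- screen_interactions(c(hp = hp))
  expect_true(sc$hairpins$hairpin[sc$hairpins$primer == "hp"])
})

test_that("multiplex groups respect annealing temperature and band spacing", {
  mk <- function(name, size, temp, f, r) {
    marker_pair(primer_candidate(paste0(name, "F"), "F", f),
                primer_candidate(paste0(name, "R"), "R", r),
                name, size, annealing_temp = temp)
  }
  # inert primer stand-ins built from {A,C} only: no base can pair with
  # any other, so grouping is decided purely by temperature and size
  seqs <- c("ACAACCACAACCACAACC", "CACCAACACCAACACCAA",
            "AACCAACCAACCAACCAA", "CCAACCAACCAACCAACC",
            "ACACACACACACACACAC", "CACACACACACACACACA")
  m65 <- list(mk("che", 396, 65, seqs[1], seqs[2]),
              mk("mur", 332, 65, seqs[3], seqs[4]),
              mk("ret", 364, 65, seqs[5], seqs[6]))
  out <- build_multiplex_groups(m65, min_separation = 30)
  expect_length(out$groups, 1)
  expect_identical(sort(out$groups[[1]]$sizes), c(332L, 364L, 396L))
  expect_gte(out$groups[[1]]$min_size_separation, 30)

  # 300 vs 310 cannot co-migrate distinguishably
  close2 <- list(mk("x", 300, 65, seqs[1], seqs[2]),
                 mk("y", 310, 65, seqs[3], seqs[4]))
  out <- build_multiplex_groups(close2, min_separation = 30)
  expect_length(out$groups, 1)
  expect_length(out$groups[[1]]$members, 1)
  expect_match(out$ungrouped$reason, "size separation")

  m69 <- list(mk("squ", 315, 69, seqs[1], seqs[2]),
              mk("mac", 644, 69, seqs[3], seqs[4]),
              mk("gla", 476, 69, seqs[5], seqs[6]))
  out <- build_multiplex_groups(m69, min_separation = 30)
  expect_length(out$groups, 1)
  expect_length(out$groups[[1]]$members, 3)
})
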