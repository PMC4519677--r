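test_that("NJ recovers the 4-taxon additive example exactly", {
  labels <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(labels, labels))
  d["A", "B"] <- 0.2; d["A", "C"] <- 0.3; d["A", "D"] <- 0.35
  d["B", "C"] <- 0.3; d["B", "D"] <- 0.35; d["C", "D"] <- 0.35
  d <- d + t(d)
  tr <- nj_tree(d)
  truth <- ape::read.tree(text = "((A:0.1,B:0.1):0.05,C:0.15,D:0.2);")
  expect_equal(ape::dist.topo(tr, truth), 0, ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(tr)[labels, labels], d,
               tolerance = 1e-12)
  # internal branch length 0.05
  internal <- tr$edge.length[tr$edge[, 2] > ape::Ntip(tr)]
  expect_equal(internal, 0.05, tolerance = 1e-12)
})

test_that("3-taxon branch lengths solve the closed-form equations", {
  labels <- c("A", "B", "C")
  d <- matrix(c(0, 0.2, 0.3, 0.2, 0, 0.4, 0.3, 0.4, 0), 3, 3,
              dimnames = list(labels, labels))
  tr <- nj_tree(d)
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(len[["A"]], 0.05, tolerance = 1e-12)
  expect_equal(len[["B"]], 0.15, tolerance = 1e-12)
  expect_equal(len[["C"]], 0.25, tolerance = 1e-12)
})

test_that("all-equal distances resolve deterministically", {
  labels <- paste0("t", 1:5)
  d <- matrix(0.1, 5, 5, dimnames = list(labels, labels)); diag(d) <- 0
  tr1 <- nj_tree(d)
  tr2 <- nj_tree(d)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  expect_true(all(tr1$edge.length >= 0))
})

test_that("random additive matrices are recovered exactly", {
  for (rep in 1:100) {
    n <- 4 + (rep %% 5)
    case <- random_additive_case(n, seed = 700 + rep)
    tr <- nj_tree(case$d)
    expect_equal(ape::dist.topo(ape::unroot(case$tree), tr), 0,
                 ignore_attr = TRUE, label = paste("topology rep", rep))
    expect_equal(ape::cophenetic.phylo(tr)[rownames(case$d), colnames(case$d)],
                 case$d, tolerance = 1e-9)
  }
})

test_that("NJ agrees with the reference implementation on noisy matrices", {
  set.seed(51)
  for (rep in 1:10) {
    case <- random_additive_case(6, seed = 800 + rep)
    noise <- matrix(stats::runif(36, 0, 0.01), 6, 6)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    d <- case$d + noise
    mine <- nj_tree(d)
    ref <- ape::nj(stats::as.dist(d))
    expect_equal(ape::dist.topo(mine, ref), 0, ignore_attr = TRUE)
  }
})

test_that("leaf-label permutation leaves the recovered topology unchanged", {
  case <- random_additive_case(7, seed = 900)
  tr1 <- nj_tree(case$d)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  d2 <- case$d[perm, perm]
  tr2 <- nj_tree(d2)
  expect_equal(ape::dist.topo(tr1, tr2), 0, ignore_attr = TRUE)
})

test_that("bootstrap supports separate clean clades and are reproducible", {
  sim <- simulate_species_set(sim_params(n_species = 2, n_per_species = 3,
                                         seq_length = 400, d_inter = 0.1,
                                         d_intra = 0,
                                         n_planted_diagnostic = 0,
                                         seed = 77))
  aln <- labeled_alignment(sim$sequences, sim$species_map)
  tr <- bootstrap_support(aln, replicates = 100, seed = 3)
  sup <- suppressWarnings(as.integer(tr$node.label))
  expect_true(any(sup >= 99, na.rm = TRUE))

  tr2 <- bootstrap_support(aln, replicates = 100, seed = 3)
  expect_identical(tr$node.label, tr2$node.label)

  tr1 <- bootstrap_support(aln, replicates = 1, seed = 9)
  sup1 <- suppressWarnings(as.integer(tr1$node.label))
  expect_true(all(sup1 %in% c(0L, 100L, NA)))
})

test_that("species monophyly is detected on any rooting", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1,c1:2);")
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C")
  mono <- species_monophyly_check(tr, sp)
  expect_true(all(mono))

  # mixed cluster: species B split across two clades
  tr <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1,c1:2);")
  mono <- species_monophyly_check(tr, sp)
  expect_false(mono[["A"]])
  expect_false(mono[["B"]])
  expect_true(mono[["C"]])          # single leaf: true by convention
})

test_that("sub-cutoff supports are blanked only in rendered output", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1,E:1);")
  tr$node.label <- c("", "49", "97")
  shown <- render_supports(tr)
  expect_identical(shown$node.label, c("", "", "97"))
})
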