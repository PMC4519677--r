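# Independent brute-force oracles used across tests. These deliberately
# re-derive results by enumeration or naive scanning, never by calling the
# implementation under test.

# retained interval under the trim-window rule, by scanning every window
oracle_trim <- function(phred, window = 10L, thr = 20L) {
  n <- length(phred)
  starts <- integer(0)
  if (n >= window) {
    for (i in 1:(n - window + 1)) {
      if (all(phred[i:(i + window - 1)] > thr)) starts <- c(starts, i)
    }
  }
  if (!length(starts)) return(c(0L, 0L))
  c(starts[1] - 1L, starts[length(starts)] + window - 1L)
}

# full QC decision by direct application of the three rules
oracle_qc <- function(bases, phred, window = 10L, thr = 20L,
                      mask_thr = 20L, max_n = 0.40) {
  r <- oracle_trim(phred, window, thr)
  if (r[2] <= r[1]) {
    return(list(status = "rejected", retained = r, sequence = "",
                n_fraction = NA_real_))
  }
  idx <- (r[1] + 1L):r[2]
  b <- strsplit(bases, "")[[1]][idx]
  b[phred[idx] < mask_thr] <- "N"
  nf <- mean(b == "N")
  list(status = if (nf > max_n) "rejected" else "accepted",
       retained = r, sequence = paste(b, collapse = ""), n_fraction = nf)
}

# optimal global alignment score by exhaustive enumeration of all monotone
# alignment paths, scoring gap runs as open + (k-1)*extend
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -5, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  recurse <- function(i, j, moves) {
    if (i > length(av) && j > length(bv)) {
      sc <- 0; prev <- ""
      ii <- 1; jj <- 1
      for (mv in moves) {
        if (mv == "D") {
          x <- av[ii]; y <- bv[jj]
          sc <- sc + if (x == y && x %in% c("A", "C", "G", "T")) match else mismatch
          ii <- ii + 1; jj <- jj + 1
        } else {
          sc <- sc + if (prev == mv) gap_extend else gap_open
          if (mv == "U") ii <- ii + 1 else jj <- jj + 1
        }
        prev <- mv
      }
      best <<- max(best, sc)
      return()
    }
    if (i <= length(av) && j <= length(bv)) recurse(i + 1, j + 1, c(moves, "D"))
    if (i <= length(av)) recurse(i + 1, j, c(moves, "U"))
    if (j <= length(bv)) recurse(i, j + 1, c(moves, "L"))
  }
  recurse(1, 1, character(0))
  best
}

# random unrooted binary tree with positive branch lengths and its
# additive (patristic) distance matrix
random_additive_case <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) stats::runif(k, 0.05, 0.5))
  tr$tip.label <- sort(tr$tip.label)   # labels independent of topology
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# naive zero-mismatch substring scan for primer binding (plus strand)
oracle_exact_sites <- function(primer, template) {
  k <- nchar(primer); L <- nchar(template)
  if (L < k) return(integer(0))
  hits <- integer(0)
  for (s in 1:(L - k + 1)) {
    if (substr(template, s, s + k - 1) == primer) hits <- c(hits, s - 1L)
  }
  hits
}

# sliding-window mismatch scan honoring the 3' clamp rule (plus strand)
oracle_mismatch_sites <- function(primer, template, max_mm, clamp) {
  pv <- strsplit(primer, "")[[1]]; tv <- strsplit(template, "")[[1]]
  k <- length(pv); L <- length(tv)
  out <- integer(0)
  if (L < k) return(out)
  for (s in 1:(L - k + 1)) {
    w <- tv[s:(s + k - 1)]
    mm <- w != pv | w == "N"
    if (sum(mm) <= max_mm && !any(mm[(k - clamp + 1):k])) out <- c(out, s - 1L)
  }
  out
}

revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(comp[rev(strsplit(s, "")[[1]])], collapse = "")
}

toy_two_species_alignment <- function() {
  rows <- c(s1a = "ACGT", s1b = "ACGT", s2a = "ACTT", s2b = "ACTT")
  labeled_alignment(rows, c(s1a = "sp1", s1b = "sp1",
                            s2a = "sp2", s2b = "sp2"))
}

# deterministic random DNA string
random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
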