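#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Exact on
#' additive matrices (recovers the generating topology and branch
#' lengths). Ties in the Q minimization are broken by the
#' lexicographically smallest label pair, where a joined node is
#' represented by the smallest label among its leaves, so the result is
#' deterministic across platforms. Negative branch lengths are clamped to
#' zero with the deficit transferred to the sister branch.
#'
#' @param dm A `DistanceMatrix` or a labelled symmetric numeric matrix.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "DistanceMatrix")) dm$d else dm
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must have labels")
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(d)) stop("undefined distances present; cannot build tree")

  nwk <- labels                # newick fragment per active node
  rep_lab <- labels            # representative (smallest) leaf label
  D <- d
  fmt <- function(x) sprintf("%.15g", x)

  while (nrow(D) > 3L) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      keys <- apply(cand, 1, function(ij) {
        p <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
        paste(p, collapse = "\r")
      })
      cand <- cand[order(keys)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; li <- max(li, 0); lj <- 0 }
    newnwk <- paste0("(", nwk[i], ":", fmt(li), ",", nwk[j], ":", fmt(lj), ")")
    newrep <- min(rep_lab[i], rep_lab[j])
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- matrix(0, r - 1, r - 1)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
    D2[r - 1, seq_along(keep)] <- newd[keep]
    D2[seq_along(keep), r - 1] <- newd[keep]
    D <- D2
    nwk <- c(nwk[keep], newnwk)
    rep_lab <- c(rep_lab[keep], newrep)
  }
  # final 3-node star: closed-form branch lengths
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  text <- paste0("(", nwk[1], ":", fmt(la), ",", nwk[2], ":", fmt(lb), ",",
                 nwk[3], ":", fmt(lc), ");")
  ape::read.tree(text = text)
}

# Canonical bipartition keys of all internal edges of an unrooted tree.
# Each split is represented by the side NOT containing the alphabetically
# first tip label, sorted and collapsed.
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(idx) {
    side <- sort(tree$tip.label[idx])
    if (anchor %in% side) side <- setdiff(tips, side)
    paste(side, collapse = "\r")
  }, "")
  # drop trivial splits (whole set, single tip complement)
  sizes <- vapply(strsplit(keys, "\r", fixed = TRUE), length, 0L)
  unique(keys[sizes >= 1 & sizes <= length(tips) - 2])
}

split_key <- function(tip_set, all_tips) {
  tips <- sort(all_tips)
  side <- sort(tip_set)
  if (tips[1] %in% side) side <- sort(setdiff(tips, side))
  paste(side, collapse = "\r")
}

# per-pair column class codes: 1 excluded, 2 identical, 3 transition,
# 4 transversion; rows indexed by pair, used for fast bootstrap resampling
pair_class_matrix <- function(m) {
  n <- nrow(m)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  cl <- matrix(1L, nrow(pairs), ncol(m))
  for (p in seq_len(nrow(pairs))) {
    a <- m[pairs[p, 1], ]; b <- m[pairs[p, 2], ]
    use <- a < 4L & b < 4L
    same <- use & a == b
    both_pur <- a %in% PURINES & b %in% PURINES
    both_pyr <- use & !(a %in% PURINES) & !(b %in% PURINES)
    ts <- use & !same & ((a %in% PURINES & b %in% PURINES) | both_pyr)
    cl[p, same] <- 2L
    cl[p, ts] <- 3L
    cl[p, use & !same & !ts] <- 4L
  }
  list(classes = cl, pairs = pairs)
}

k2p_from_class_counts <- function(counts) {
  n <- counts[2] + counts[3] + counts[4]
  if (n == 0) return(NA_real_)
  P <- counts[3] / n; Q <- counts[4] / n
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Alignment columns are resampled with replacement `replicates` times;
#' each replicate gets its own K2P distance matrix and NJ tree. The
#' support of each internal edge of the point-estimate tree is the
#' percentage of replicate trees containing the same bipartition.
#' Replicates with saturated (undefined) distances are dropped and
#' counted with a warning. Fully reproducible under a fixed seed.
#'
#' @param aln A `LabeledAlignment`.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer RNG seed.
#' @param model Distance model passed through ("K2P" or "p").
#' @return The point-estimate `phylo` tree with integer percent supports
#'   in `node.label` (root label empty) and attributes
#'   `bootstrap_replicates_used` and `bootstrap_replicates_dropped`.
#' @export
bootstrap_support <- function(aln, replicates = 1000L, seed = 1L,
                              model = "K2P") {
  if (length(aln$rows) < 3L) stop("need at least 3 rows")
  dm <- distance_matrix(aln, model = model, strict = TRUE)
  point <- nj_tree(dm)
  m <- alignment_matrix(aln)
  pcm <- pair_class_matrix(m)
  n <- nrow(m)
  labels <- rownames(m)
  all_tips <- labels
  point_keys <- tree_splits(point)
  counts <- stats::setNames(rep(0L, length(point_keys)), point_keys)

  set.seed(seed)
  dropped <- 0L
  for (b in seq_len(replicates)) {
    idx <- sample.int(ncol(m), ncol(m), replace = TRUE)
    cl <- pcm$classes[, idx, drop = FALSE]
    dvals <- apply(cl, 1, function(v) k2p_from_class_counts(tabulate(v, 4L)))
    if (model == "p") {
      dvals <- apply(cl, 1, function(v) {
        tb <- tabulate(v, 4L); nn <- sum(tb[2:4])
        if (nn == 0) NA_real_ else (tb[3] + tb[4]) / nn
      })
    }
    if (anyNA(dvals)) { dropped <- dropped + 1L; next }
    D <- matrix(0, n, n, dimnames = list(labels, labels))
    D[pcm$pairs] <- dvals
    D <- D + t(D)
    rep_tree <- nj_tree(D)
    rep_keys <- tree_splits(rep_tree)
    hit <- point_keys %in% rep_keys
    counts[hit] <- counts[hit] + 1L
  }
  used <- replicates - dropped
  if (dropped > 0L) {
    warning(dropped, " bootstrap replicate(s) dropped (saturated distances)")
  }
  support <- if (used > 0) round(100 * counts / used) else counts * NA_real_

  # map supports onto internal nodes of the point tree
  node_labels <- character(point$Nnode)
  parts <- ape::prop.part(point)
  for (k in seq_along(parts)) {
    key <- split_key(point$tip.label[parts[[k]]], all_tips)
    node_labels[k] <- if (key %in% names(support)) {
      as.character(as.integer(support[[key]]))
    } else ""                       # root / trivial partition
  }
  point$node.label <- node_labels
  attr(point, "bootstrap_replicates_used") <- used
  attr(point, "bootstrap_replicates_dropped") <- dropped
  point
}

#' Per-species monophyly on an unrooted tree
#'
#' A species is monophyletic when its leaves form a clade on some rooting,
#' i.e. a single bipartition of the tree separates exactly that species.
#' Single-leaf species are monophyletic by convention.
#'
#' @param tree An `ape::phylo` tree.
#' @param species_of Named character vector sample_id -> species.
#' @return Named logical vector, one element per species.
#' @export
species_monophyly_check <- function(tree, species_of) {
  if (inherits(species_of, "data.frame")) species_of <- species_lookup(species_of)
  sp <- species_of[tree$tip.label]
  keys <- tree_splits(tree)
  out <- vapply(unique(sp), function(s) {
    tipset <- tree$tip.label[sp == s]
    if (length(tipset) <= 1L || length(tipset) >= length(tree$tip.label) - 1L) {
      return(TRUE)
    }
    split_key(tipset, tree$tip.label) %in% keys
  }, logical(1))
  names(out) <- unique(sp)
  out
}

#' Render supports for display: values below a cutoff suppressed
#'
#' Machine output keeps all supports; rendered output conventionally shows
#' only supports at or above 50 percent.
#'
#' @param tree A `phylo` with `node.label` supports.
#' @param cutoff Minimum support to display.
#' @return The tree with sub-cutoff `node.label`s blanked.
#' @export
render_supports <- function(tree, cutoff = 50) {
  lab <- suppressWarnings(as.integer(tree$node.label))
  tree$node.label <- ifelse(!is.na(lab) & lab >= cutoff,
                            as.character(lab), "")
  tree
}
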