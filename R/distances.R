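PURINES <- c(0L, 2L)   # A, G codes

#' Transition/transversion counts for one aligned pair
#'
#' Columns where either row carries a gap or `N` are excluded (pairwise
#' deletion). `P` is the proportion of compared sites showing a transition
#' (A<->G, C<->T), `Q` the proportion showing a transversion.
#'
#' @param row_a,row_b Equal-length gapped sequence strings.
#' @return List of class `PairCounts`: `P`, `Q`, `n` (compared sites).
#'   `n == 0` yields `P = Q = NA` (undefined-pair signal).
#' @export
pair_counts <- function(row_a, row_b) {
  a <- encode_seq(row_a); b <- encode_seq(row_b)
  if (length(a) != length(b)) stop("rows differ in length")
  use <- a < 4L & b < 4L
  n <- sum(use)
  if (n == 0L) {
    return(structure(list(P = NA_real_, Q = NA_real_, n = 0L),
                     class = "PairCounts"))
  }
  a <- a[use]; b <- b[use]
  diff <- a != b
  both_pur <- a %in% PURINES & b %in% PURINES
  both_pyr <- !(a %in% PURINES) & !(b %in% PURINES)
  ts <- diff & (both_pur | both_pyr)
  structure(list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n = n),
            class = "PairCounts")
}

#' Kimura 2-parameter distance from transition/transversion proportions
#'
#' d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q)). Saturated pairs (either
#' logarithm argument <= 0) return `NA` with a warning rather than a
#' silent `NaN`, so downstream extrema never absorb corrupt values.
#'
#' @param counts A `PairCounts`, or a list with elements `P` and `Q`.
#' @return Distance in substitutions/site, or `NA` on saturation.
#' @export
k2p <- function(counts) {
  P <- counts$P; Q <- counts$Q
  if (is.na(P) || is.na(Q)) return(NA_real_)
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P saturation: distance undefined (P=", P, ", Q=", Q, ")")
    return(NA_real_)
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Observed proportion of differing sites (p-distance)
#' @inheritParams k2p
#' @return P + Q, or `NA` for an undefined pair.
#' @export
p_distance <- function(counts) {
  if (is.na(counts$P)) return(NA_real_)
  counts$P + counts$Q
}

# integer matrix (rows x columns) from a LabeledAlignment
alignment_matrix <- function(aln) {
  m <- do.call(rbind, lapply(aln$rows, encode_seq))
  rownames(m) <- names(aln$rows)
  m
}

pair_counts_codes <- function(a, b) {
  use <- a < 4L & b < 4L
  n <- sum(use)
  if (n == 0L) return(list(P = NA_real_, Q = NA_real_, n = 0L))
  a <- a[use]; b <- b[use]
  diff <- a != b
  both_pur <- a %in% PURINES & b %in% PURINES
  both_pyr <- !(a %in% PURINES) & !(b %in% PURINES)
  ts <- diff & (both_pur | both_pyr)
  list(P = sum(ts) / n, Q = sum(diff & !ts) / n, n = n)
}

#' Pairwise distance matrix from a labelled alignment
#'
#' Computes all pairwise distances under the chosen model with pairwise
#' deletion of gap/N columns. Undefined pairs (no comparable sites, or K2P
#' saturation) are reported as `NA`; with `strict = TRUE` they abort.
#'
#' @param aln A `LabeledAlignment`.
#' @param model "K2P" (default) or "p".
#' @param strict Abort on any undefined pair.
#' @return List of class `DistanceMatrix`: `labels`, `d` (symmetric
#'   matrix), `sites_used` (per-pair compared-site counts), `model`,
#'   `species_of`.
#' @export
distance_matrix <- function(aln, model = c("K2P", "p"), strict = FALSE) {
  model <- match.arg(model)
  if (length(aln$rows) < 2L) stop("need at least 2 rows")
  m <- alignment_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sites <- matrix(NA_integer_, n, n, dimnames = dimnames(d))
  diag(sites) <- ncol(m)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pc <- pair_counts_codes(m[i, ], m[j, ])
    sites[i, j] <- sites[j, i] <- pc$n
    val <- if (model == "K2P") k2p(pc) else p_distance(pc)
    d[i, j] <- d[j, i] <- val
  }
  if (strict && anyNA(d)) {
    bad <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    stop("undefined distance for pair(s): ",
         paste(rownames(m)[bad[, 1]], rownames(m)[bad[, 2]],
               sep = "~", collapse = ", "))
  }
  structure(list(labels = rownames(m), d = d, sites_used = sites,
                 model = model, species_of = aln$species_of),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat(sprintf("DistanceMatrix (%s): %d labels, mean off-diagonal %.4f\n",
              x$model, length(x$labels),
              mean(x$d[upper.tri(x$d)], na.rm = TRUE)))
  invisible(x)
}

#' Per-pair P/Q/n detail table
#'
#' @param aln A `LabeledAlignment`.
#' @return data.frame with one row per unordered pair: sample_a, sample_b,
#'   P, Q, n, k2p, p.
#' @export
pair_detail <- function(aln) {
  m <- alignment_matrix(aln)
  n <- nrow(m)
  rows <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pc <- pair_counts_codes(m[i, ], m[j, ])
    rows[[length(rows) + 1L]] <- data.frame(
      sample_a = rownames(m)[i], sample_b = rownames(m)[j],
      P = pc$P, Q = pc$Q, n = pc$n,
      k2p = suppressWarnings(k2p(pc)), p = p_distance(pc),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
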