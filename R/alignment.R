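BASE_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L, N = 4L, `-` = 5L)

encode_seq <- function(s) {
  v <- BASE_CODES[strsplit(s, "", fixed = TRUE)[[1]]]
  if (anyNA(v)) stop("cannot encode sequence: illegal character")
  unname(v)
}

decode_seq <- function(codes) {
  paste(names(BASE_CODES)[codes + 1L], collapse = "")
}

#' Alignment scoring parameters
#'
#' Simple match/mismatch scoring with affine gap costs; a gap of length k
#' costs `gap_open + (k - 1) * gap_extend`.
#'
#' @param match Match score.
#' @param mismatch Mismatch score (N mismatches everything).
#' @param gap_open Cost of the first column of a gap (negative).
#' @param gap_extend Cost of each further gap column (negative).
#' @return List of class `AlignParams`.
#' @export
align_params <- function(match = 1, mismatch = -1, gap_open = -5,
                         gap_extend = -1) {
  stopifnot(gap_open <= gap_extend, gap_extend <= 0, 0 <= match)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "AlignParams")
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch with affine gaps (Gotoh). Deterministic traceback with
#' tie preference diagonal > up > left.
#'
#' @param a,b Ungapped nucleotide strings.
#' @param params An `AlignParams`.
#' @return List: `a_gapped`, `b_gapped`, `score`.
#' @export
pairwise_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align empty sequence")
  pa <- matrix(encode_seq(a), nrow = 1)
  pb <- matrix(encode_seq(b), nrow = 1)
  res <- .align_profiles_cpp(pa, pb, params$match, params$mismatch,
                             params$gap_open, params$gap_extend)
  av <- ifelse(res$a_cols == 0L, 5L, pa[1, pmax(res$a_cols, 1L)])
  bv <- ifelse(res$b_cols == 0L, 5L, pb[1, pmax(res$b_cols, 1L)])
  list(a_gapped = decode_seq(av), b_gapped = decode_seq(bv),
       score = res$score)
}

#' Construct a LabeledAlignment
#'
#' @param rows Named character vector of equal-length gapped sequences.
#' @param species_of Named character vector mapping every sample_id to a
#'   species label, or a `species_map` data.frame.
#' @return List of class `LabeledAlignment` with `rows`, `column_count`,
#'   `species_of`.
#' @export
labeled_alignment <- function(rows, species_of) {
  if (inherits(species_of, "data.frame")) species_of <- species_lookup(species_of)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: row lengths ", paste(unique(lens), collapse = ", "))
  }
  missing <- setdiff(names(rows), names(species_of))
  if (length(missing)) {
    stop("sample(s) without species label: ", paste(missing, collapse = ", "))
  }
  structure(list(rows = rows, column_count = unname(lens[1]),
                 species_of = species_of[names(rows)]),
            class = "LabeledAlignment")
}

#' @export
print.LabeledAlignment <- function(x, ...) {
  cat(sprintf("LabeledAlignment: %d rows x %d columns, %d species\n",
              length(x$rows), x$column_count,
              length(unique(x$species_of))))
  invisible(x)
}

#' Ingest a pre-aligned FASTA with species labels
#'
#' @param path Path to an aligned (equal-length, gapped) FASTA.
#' @param species_map A `species_map` data.frame or named character vector.
#' @return A `LabeledAlignment`.
#' @export
ingest_alignment <- function(path, species_map) {
  rows <- read_fasta(path)
  labeled_alignment(rows, species_map)
}

# UPGMA guide tree on a distance matrix; returns merge list (each element
# a pair of cluster indices in the running cluster list). Ties broken by
# input order (smallest first index, then smallest second).
upgma_merge_order <- function(d) {
  n <- nrow(d)
  active <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  dm <- d
  merges <- list()
  repeat {
    k <- length(active)
    if (k == 1L) break
    best <- c(NA, NA); bestv <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (dm[i, j] < bestv - 1e-12) { bestv <- dm[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    merges[[length(merges) + 1L]] <- c(i, j)
    # new cluster distances: size-weighted average (UPGMA)
    newd <- (sizes[i] * dm[i, ] + sizes[j] * dm[j, ]) / (sizes[i] + sizes[j])
    keep <- setdiff(seq_len(k), c(i, j))
    dm2 <- matrix(0, k - 1, k - 1)
    if (length(keep)) {
      dm2[seq_along(keep), seq_along(keep)] <- dm[keep, keep, drop = FALSE]
      dm2[k - 1, seq_along(keep)] <- newd[keep]
      dm2[seq_along(keep), k - 1] <- newd[keep]
    }
    dm <- dm2
    sizes <- c(sizes[keep], sizes[i] + sizes[j])
    active <- c(active[keep], list(c(active[[i]], active[[j]])))
  }
  merges
}

#' Progressive multiple sequence alignment
#'
#' Native replacement for an external aligner: pairwise p-distances from
#' global pairwise alignments feed a UPGMA guide tree, and profiles are
#' merged in guide-tree order with affine-gap profile alignment. Columns
#' that are all-gap are never produced. Guide-tree ties are broken by
#' input order, so the result is deterministic.
#'
#' @param seqs Named character vector of >= 2 ungapped sequences.
#' @param params An `AlignParams`.
#' @param species_of Optional species labels; when given, the return value
#'   is a `LabeledAlignment`, otherwise a named character vector.
#' @return Aligned rows (all the same length) in input order.
#' @export
progressive_msa <- function(seqs, params = align_params(), species_of = NULL) {
  n <- length(seqs)
  if (n < 2L) stop("progressive_msa needs at least 2 sequences")
  enc <- lapply(seqs, encode_seq)
  # guide distances: p-distance on pairwise alignments
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pw <- pairwise_align(seqs[[i]], seqs[[j]], params)
    av <- encode_seq(pw$a_gapped); bv <- encode_seq(pw$b_gapped)
    cmp <- av != 5L & bv != 5L & av != 4L & bv != 4L
    d[i, j] <- d[j, i] <- if (any(cmp)) mean(av[cmp] != bv[cmp]) else 1
  }
  merges <- upgma_merge_order(d)
  # clusters: list(members = indices, profile = int matrix)
  clusters <- lapply(seq_len(n), function(i) {
    list(members = i, profile = matrix(enc[[i]], nrow = 1))
  })
  for (mg in merges) {
    a <- clusters[[mg[1]]]; b <- clusters[[mg[2]]]
    res <- .align_profiles_cpp(a$profile, b$profile, params$match,
                               params$mismatch, params$gap_open,
                               params$gap_extend)
    la <- length(res$a_cols)
    newprof <- matrix(5L, nrow = nrow(a$profile) + nrow(b$profile), ncol = la)
    sel <- res$a_cols > 0L
    newprof[seq_len(nrow(a$profile)), sel] <- a$profile[, res$a_cols[sel], drop = FALSE]
    sel <- res$b_cols > 0L
    newprof[nrow(a$profile) + seq_len(nrow(b$profile)), sel] <-
      b$profile[, res$b_cols[sel], drop = FALSE]
    keep <- setdiff(seq_along(clusters), mg)
    clusters <- c(clusters[keep],
                  list(list(members = c(a$members, b$members), profile = newprof)))
  }
  final <- clusters[[1]]
  ord <- order(final$members)
  rows <- vapply(ord, function(r) decode_seq(final$profile[r, ]), "")
  names(rows) <- names(seqs)[final$members[ord]]
  rows <- rows[names(seqs)]
  if (is.null(species_of)) rows else labeled_alignment(rows, species_of)
}
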