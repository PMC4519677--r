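#' QC parameters for barcode sequence acceptance
#'
#' Encodes the three acceptance criteria applied to single-read barcode
#' chromatogram sequences: (i) ends are trimmed until at least `window`
#' contiguous bases have PHRED score strictly greater than
#' `window_min_phred`; (ii) retained bases with score strictly below
#' `mask_below_phred` are recorded as `N`; (iii) sequences with an
#' N-fraction strictly above `max_n_fraction` are rejected. Note the
#' asymmetry at a score of exactly 20 under the defaults: it cannot anchor
#' a trim window (strict `> 20`) but is not masked (strict `< 20`).
#'
#' @param window Run length of the trim window (bases).
#' @param window_min_phred Exclusive PHRED threshold for the trim window.
#' @param mask_below_phred Exclusive PHRED threshold for masking.
#' @param max_n_fraction Exclusive upper bound on the N fraction.
#' @return List of class `QCParams`.
#' @export
qc_params <- function(window = 10L, window_min_phred = 20L,
                      mask_below_phred = 20L, max_n_fraction = 0.40) {
  stopifnot(window >= 1L,
            window_min_phred >= 0L, window_min_phred <= 93L,
            mask_below_phred >= 0L, mask_below_phred <= 93L,
            max_n_fraction > 0, max_n_fraction <= 1)
  structure(list(window = as.integer(window),
                 window_min_phred = as.integer(window_min_phred),
                 mask_below_phred = as.integer(mask_below_phred),
                 max_n_fraction = max_n_fraction),
            class = "QCParams")
}

# Start positions (1-based) of every qualifying window of `w` consecutive
# scores strictly above `thr`.
qualifying_window_starts <- function(phred, w, thr) {
  n <- length(phred)
  if (n < w) return(integer(0))
  ok <- as.integer(phred > thr)
  run <- cumsum(ok)
  sums <- run[w:n] - c(0L, run)[1:(n - w + 1L)]
  which(sums == w)
}

#' Trim low-quality sequence ends
#'
#' Retains the maximal interval bounded by the outermost qualifying
#' windows: from the start of the first run of `window` consecutive bases
#' all scoring strictly above `window_min_phred`, to the end of the last
#' such run. If no qualifying window exists the retained interval is empty
#' (a valid state; the sequence is rejected downstream).
#'
#' @param qseq A `QualitySequence`.
#' @param params A `QCParams`.
#' @return The `QualitySequence` with `trimmed_range` updated.
#' @export
trim_ends <- function(qseq, params = qc_params()) {
  starts <- qualifying_window_starts(qseq$phred, params$window,
                                     params$window_min_phred)
  if (!length(starts)) {
    qseq$trimmed_range <- c(0L, 0L)
  } else {
    first <- starts[1]
    last_end <- starts[length(starts)] + params$window - 1L
    # 0-based half-open
    qseq$trimmed_range <- c(first - 1L, last_end)
  }
  qseq$n_fraction <- retained_n_fraction(qseq$bases, qseq$trimmed_range)
  qseq
}

#' Mask low-quality retained bases as N
#'
#' Every retained base with PHRED score strictly below `mask_below_phred`
#' becomes `N`. Trimming decisions are made on raw scores first, so masking
#' never influences the retained interval.
#'
#' @inheritParams trim_ends
#' @return The `QualitySequence` with bases masked and `masked_count` set.
#' @export
mask_low_quality <- function(qseq, params = qc_params()) {
  r <- qseq$trimmed_range
  if (r[2] > r[1]) {
    idx <- seq(r[1] + 1L, r[2])
    low <- idx[qseq$phred[idx] < params$mask_below_phred]
    if (length(low)) {
      b <- strsplit(qseq$bases, "")[[1]]
      already_n <- b[low] == "N"
      b[low] <- "N"
      qseq$bases <- paste(b, collapse = "")
      qseq$masked_count <- qseq$masked_count + sum(!already_n)
    }
  }
  qseq$n_fraction <- retained_n_fraction(qseq$bases, qseq$trimmed_range)
  qseq
}

#' Accept or reject a trimmed, masked sequence
#'
#' Rejected iff the retained interval is empty or the N fraction among
#' retained bases strictly exceeds `max_n_fraction`. Input `N`s count
#' toward the fraction exactly like masked ones.
#'
#' @inheritParams trim_ends
#' @return List of class `QCResult`: `status` ("accepted"/"rejected"),
#'   `sequence` (retained bases), `masked_count`, `n_fraction`, `reason`.
#' @export
accept_or_reject <- function(qseq, params = qc_params()) {
  r <- qseq$trimmed_range
  if (r[2] <= r[1]) {
    return(structure(list(sample_id = qseq$sample_id, status = "rejected",
                          sequence = "", masked_count = qseq$masked_count,
                          n_fraction = NA_real_, trimmed_range = r,
                          reason = "no qualifying window"),
                     class = "QCResult"))
  }
  nf <- retained_n_fraction(qseq$bases, r)
  if (nf > params$max_n_fraction) {
    status <- "rejected"
    reason <- sprintf("N fraction %.3f exceeds %.3f", nf, params$max_n_fraction)
  } else {
    status <- "accepted"
    reason <- ""
  }
  structure(list(sample_id = qseq$sample_id, status = status,
                 sequence = substr(qseq$bases, r[1] + 1L, r[2]),
                 masked_count = qseq$masked_count, n_fraction = nf,
                 trimmed_range = r, reason = reason),
            class = "QCResult")
}

#' Full QC pass: trim, mask, accept/reject
#'
#' @param qseq A `QualitySequence` (raw, untrimmed).
#' @param params A `QCParams`.
#' @return A `QCResult`.
#' @export
run_qc <- function(qseq, params = qc_params()) {
  accept_or_reject(mask_low_quality(trim_ends(qseq, params), params), params)
}

#' Run QC over a set of sequences and write report rows
#'
#' @param qseqs List of `QualitySequence`.
#' @param params A `QCParams`.
#' @return data.frame with one row per input: sample_id, status,
#'   retained_start, retained_end (0-based half-open), masked, n_fraction,
#'   reason.
#' @export
qc_report <- function(qseqs, params = qc_params()) {
  rows <- lapply(qseqs, function(q) {
    res <- run_qc(q, params)
    data.frame(sample_id = res$sample_id, status = res$status,
               retained_start = res$trimmed_range[1],
               retained_end = res$trimmed_range[2],
               masked = res$masked_count,
               n_fraction = res$n_fraction,
               reason = res$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Accepted sequences from a QC run, as a named character vector
#' @inheritParams qc_report
#' @export
qc_accepted <- function(qseqs, params = qc_params()) {
  out <- list()
  for (q in qseqs) {
    res <- run_qc(q, params)
    if (res$status == "accepted") out[[res$sample_id]] <- res$sequence
  }
  unlist(out)
}
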