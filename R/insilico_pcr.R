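#' Parameters for in-silico PCR
#'
#' The default is exact-match binding (`max_mismatch = 0`); when
#' mismatches are tolerated, the 3'-terminal `clamp` bases must still
#' match perfectly, since 3' mismatches abolish polymerase extension.
#' An `N` in the template never matches any primer base.
#'
#' @param max_mismatch Maximum mismatches outside the clamp.
#' @param clamp Number of 3'-terminal primer bases requiring a perfect
#'   match.
#' @param max_product Maximum reported amplicon length (bp).
#' @return List of class `PcrParams`.
#' @export
pcr_params <- function(max_mismatch = 0L, clamp = 3L, max_product = 5000L) {
  structure(list(max_mismatch = as.integer(max_mismatch),
                 clamp = as.integer(clamp),
                 max_product = as.integer(max_product)),
            class = "PcrParams")
}

# mismatch count of `primer` against every window of `template` (encoded
# integer vectors); template N (code 4) never matches
window_mismatches <- function(tmpl, prim) {
  L <- length(tmpl); k <- length(prim)
  if (L < k) return(list(total = integer(0), tail = integer(0)))
  n_win <- L - k + 1L
  total <- integer(n_win)
  for (i in seq_len(k)) {
    total <- total + (tmpl[i:(i + n_win - 1L)] != prim[i])
  }
  total
}

window_mismatches_region <- function(tmpl, prim, pos_subset) {
  L <- length(tmpl); k <- length(prim)
  n_win <- L - k + 1L
  out <- integer(n_win)
  for (i in pos_subset) {
    out <- out + (tmpl[i:(i + n_win - 1L)] != prim[i])
  }
  out
}

#' Find primer binding sites on a template
#'
#' Forward (plus-strand) sites are positions where the primer matches the
#' template; reverse (minus-strand) sites are positions where the
#' primer's reverse complement appears on the plus strand. `start` is the
#' 0-based position of the site's 5'-most (leftmost) template base.
#'
#' @param primer Gap-free A/C/G/T primer, 5'->3'.
#' @param template Ungapped template sequence (may contain N).
#' @param params A `PcrParams`.
#' @return data.frame: `strand` ("plus"/"minus"), `start`, `end` (0-based
#'   inclusive), `mismatches`, `three_prime_clamp_ok`.
#' @export
find_binding_sites <- function(primer, template, params = pcr_params()) {
  prim <- encode_seq(toupper(primer))
  if (any(prim > 3L)) stop("primer must be unambiguous A/C/G/T")
  tmpl <- encode_seq(toupper(template))
  if (any(tmpl == 5L)) stop("template must be ungapped")
  k <- length(prim)
  out <- list()
  scan <- function(pr, strand) {
    total <- window_mismatches(tmpl, pr)
    if (!length(total)) return()
    # clamp positions within the site: for a plus-strand site the primer
    # 3' end is the site's right edge; for a minus-strand site (revcomp
    # matched on plus strand) the primer 3' end is the site's left edge
    clamp_pos <- if (strand == "plus") (k - params$clamp + 1L):k else 1:params$clamp
    clamp_mm <- window_mismatches_region(tmpl, pr, clamp_pos)
    hits <- which(total <= params$max_mismatch & clamp_mm == 0L)
    for (h in hits) {
      out[[length(out) + 1L]] <<- data.frame(
        strand = strand, start = h - 1L, end = h + k - 2L,
        mismatches = total[h], three_prime_clamp_ok = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  scan(prim, "plus")
  scan(encode_seq(reverse_complement(primer)), "minus")
  if (!length(out)) {
    return(data.frame(strand = character(0), start = integer(0),
                      end = integer(0), mismatches = integer(0),
                      three_prime_clamp_ok = logical(0)))
  }
  do.call(rbind, out)
}

#' Predict PCR amplicons of a primer pair on a template
#'
#' All pairings of a forward plus-strand site with a reverse minus-strand
#' site lying downstream are reported, up to `max_product`. The product
#' length convention is gel-facing: inclusive of both primer footprints,
#' `rev_end - fwd_start + 1` in plus-strand coordinates.
#'
#' @param fwd,rev Primer sequences 5'->3'.
#' @param template Ungapped template.
#' @param params A `PcrParams`.
#' @return data.frame: `fwd_start`, `rev_end` (0-based), `product_length`.
#' @export
predict_amplicons <- function(fwd, rev, template, params = pcr_params()) {
  fs <- find_binding_sites(fwd, template, params)
  rs <- find_binding_sites(rev, template, params)
  fs <- fs[fs$strand == "plus", , drop = FALSE]
  rs <- rs[rs$strand == "minus", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(fs))) for (j in seq_len(nrow(rs))) {
    if (rs$start[j] <= fs$start[i]) next
    len <- rs$end[j] - fs$start[i] + 1L
    if (len > params$max_product) next
    if (len < max(nchar(fwd), nchar(rev))) next
    out[[length(out) + 1L]] <- data.frame(
      fwd_start = fs$start[i], rev_end = rs$end[j],
      product_length = len, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(fwd_start = integer(0), rev_end = integer(0),
                      product_length = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$product_length), , drop = FALSE]
}

#' Marker-by-sample specificity matrix
#'
#' Runs every marker's primer pair against every template and records the
#' predicted product lengths (sorted ascending; an empty cell means no
#' band). A marker is "specific" when every target-species template
#' yields exactly one product and every non-target template yields none.
#'
#' @param markers List of `MarkerPair`s.
#' @param templates Named character vector of ungapped template sequences.
#' @param species_of Named character vector sample_id -> species.
#' @param params A `PcrParams`.
#' @return List of class `SpecificityMatrix`: `cells` (list-matrix of
#'   length vectors), `markers`, `samples`, `species_of`, `specific`
#'   (named logical per marker).
#' @export
specificity_matrix <- function(markers, templates, species_of,
                               params = pcr_params()) {
  if (inherits(species_of, "data.frame")) species_of <- species_lookup(species_of)
  stopifnot(length(markers) >= 1L, length(templates) >= 1L)
  mnames <- vapply(markers, `[[`, "", "name")
  snames <- names(templates)
  ord <- order(species_of[snames], snames)   # columns grouped by species
  snames <- snames[ord]
  cells <- matrix(vector("list", length(markers) * length(snames)),
                  nrow = length(markers),
                  dimnames = list(mnames, snames))
  for (i in seq_along(markers)) {
    for (s in snames) {
      preds <- predict_amplicons(markers[[i]]$forward$sequence,
                                 markers[[i]]$reverse$sequence,
                                 templates[[s]], params)
      cells[[i, s]] <- sort(preds$product_length)
    }
  }
  specific <- vapply(seq_along(markers), function(i) {
    tgt <- species_of[snames] == markers[[i]]$target_species
    all(lengths(cells[i, snames[tgt]]) == 1L) &&
      all(lengths(cells[i, snames[!tgt]]) == 0L)
  }, logical(1))
  names(specific) <- mnames
  structure(list(cells = cells, markers = mnames, samples = snames,
                 species_of = species_of, specific = specific),
            class = "SpecificityMatrix")
}

#' @export
print.SpecificityMatrix <- function(x, ...) {
  disp <- apply(x$cells, c(1, 2), function(v) paste(v[[1]], collapse = ","))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Write a specificity matrix TSV
#' @param smat A `SpecificityMatrix`.
#' @param path Output path.
#' @export
write_specificity_tsv <- function(smat, path) {
  disp <- apply(smat$cells, c(1, 2), function(v) paste(v[[1]], collapse = ","))
  df <- data.frame(marker = rownames(disp), disp, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Infer the maternal parent of a hybrid from chloroplast markers
#'
#' Chloroplast inheritance is maternal, so among the candidate parents'
#' species-specific plastid markers exactly one should amplify on a
#' hybrid's template: that marker's target species is the maternal (seed)
#' parent, and the other candidate is the pollen donor. Zero or more than
#' one amplifying marker is inconclusive.
#'
#' @param hybrid_template Ungapped template sequence of the hybrid.
#' @param candidate_markers List of `MarkerPair`s for >= 2 candidate
#'   parent species.
#' @param params A `PcrParams`.
#' @return List: `maternal` (species label or NA), `status`
#'   ("resolved"/"inconclusive"), `amplified` (character vector of
#'   amplifying marker target species).
#' @export
infer_maternal_parent <- function(hybrid_template, candidate_markers,
                                  params = pcr_params()) {
  targets <- vapply(candidate_markers, `[[`, "", "target_species")
  if (length(unique(targets)) < 2L) {
    stop("need markers for at least 2 candidate parent species")
  }
  amp <- vapply(candidate_markers, function(mp) {
    nrow(predict_amplicons(mp$forward$sequence, mp$reverse$sequence,
                           hybrid_template, params)) > 0L
  }, logical(1))
  hit <- unique(targets[amp])
  if (length(hit) == 1L) {
    list(maternal = hit, status = "resolved", amplified = hit)
  } else {
    if (length(hit) > 1L) {
      warning("markers of multiple candidate species amplified: ",
              paste(hit, collapse = ", "))
    }
    list(maternal = NA_character_, status = "inconclusive", amplified = hit)
  }
}
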