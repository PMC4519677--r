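#' Barcoding-gap analysis per species
#'
#' For each species, collects within-species pairwise distances (intra)
#' and distances between that species and all others (inter), and applies
#' the discrimination criterion: a species is discriminated when its
#' maximum intraspecific distance is strictly lower than its minimum
#' interspecific distance. Species represented by a single sample have no
#' intraspecific pairs and are reported as not assessable. Undefined (NA)
#' distances are excluded from the extrema with a warning.
#'
#' @param dm A `DistanceMatrix`.
#' @param species_of Named character vector sample_id -> species; defaults
#'   to the labels attached to `dm`.
#' @return data.frame of class `GapReport`, one row per species:
#'   `species`, `n_samples`, `min_intra`, `max_intra`, `min_inter`,
#'   `max_inter`, `discriminated` (logical, NA = not assessable).
#' @export
gap_analysis <- function(dm, species_of = dm$species_of) {
  if (is.null(species_of)) stop("no species labels supplied")
  if (inherits(species_of, "data.frame")) species_of <- species_lookup(species_of)
  unlabeled <- setdiff(dm$labels, names(species_of))
  if (length(unlabeled)) {
    stop("labels without species: ", paste(unlabeled, collapse = ", "))
  }
  sp <- species_of[dm$labels]
  if (length(unique(sp)) < 2L) {
    stop("gap analysis needs at least 2 species (no interspecific pairs)")
  }
  if (anyNA(dm$d[upper.tri(dm$d)])) {
    warning("undefined distances excluded from gap extrema")
  }
  rows <- lapply(unique(sp), function(s) {
    inside <- which(sp == s)
    outside <- which(sp != s)
    intra <- if (length(inside) > 1L) {
      dm$d[inside, inside][upper.tri(diag(length(inside)))]
    } else numeric(0)
    inter <- as.vector(dm$d[inside, outside, drop = FALSE])
    intra <- intra[!is.na(intra)]
    inter <- inter[!is.na(inter)]
    max_intra <- if (length(intra)) max(intra) else NA_real_
    min_intra <- if (length(intra)) min(intra) else NA_real_
    min_inter <- if (length(inter)) min(inter) else NA_real_
    max_inter <- if (length(inter)) max(inter) else NA_real_
    discriminated <- if (is.na(max_intra) || is.na(min_inter)) {
      NA                                  # single-sample: not assessable
    } else max_intra < min_inter          # strict inequality
    data.frame(species = s, n_samples = length(inside),
               min_intra = min_intra, max_intra = max_intra,
               min_inter = min_inter, max_inter = max_inter,
               discriminated = discriminated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("GapReport", "data.frame")
  out
}

#' Number of species successfully discriminated
#'
#' @param reports A `GapReport` (from [gap_analysis()]).
#' @return Integer count of species with a verdict of TRUE.
#' @export
discrimination_count <- function(reports) {
  if (nrow(reports) < 1L) stop("empty report")
  sum(reports$discriminated %in% TRUE)
}

#' Write a per-species gap report TSV
#' @param reports A `GapReport`.
#' @param path Output path.
#' @export
write_gap_tsv <- function(reports, path) {
  out <- reports
  for (col in c("min_intra", "max_intra", "min_inter", "max_inter")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         format(round(out[[col]], 6), nsmall = 6,
                                trim = TRUE, scientific = FALSE))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
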