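#' Nearest-neighbor melting temperature parameters
#'
#' Duplex Tm is computed as
#' `Tm = 1000*(dH + dH_init) / (dS + dS_init + R*ln(CT/4)) - 273.15
#'  + 16.6*log10(Na)`,
#' with dH/dS summed over the Breslauer (1986) dinucleotide stack table
#' (kcal/mol and cal/mol/K). The default parameter set was calibrated once
#' against a reference panel of 14 species-specific chloroplast primers
#' with known Tm values (see `scripts/calibrate_tm.R`): helix initiation
#' dH_init = -3.4 kcal/mol, dS_init = -10.8 cal/mol/K, total strand
#' concentration 5.5 nM, monovalent cation 50 mM. Under this set the whole
#' panel is reproduced within 0.07 degrees C.
#'
#' @param dH_init Helix-initiation enthalpy (kcal/mol).
#' @param dS_init Helix-initiation entropy (cal/mol/K).
#' @param ct Total strand concentration (mol/L); the symmetry factor
#'   CT/4 for non-self-complementary duplexes is applied internally.
#' @param na Monovalent cation concentration (mol/L).
#' @return List of class `TmParams`.
#' @export
tm_params <- function(dH_init = -3.4, dS_init = -10.8, ct = 5.5e-9,
                      na = 0.05) {
  stopifnot(ct > 0, na > 0)
  structure(list(dH_init = dH_init, dS_init = dS_init, ct = ct, na = na),
            class = "TmParams")
}

# Breslauer et al. (1986) nearest-neighbor stacks: dH kcal/mol, dS cal/mol/K
BRESLAUER_DH <- c(AA = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, GT = -6.5,
                  CT = -7.8, GA = -5.6, CG = -11.9, GC = -11.1, GG = -11.0)
BRESLAUER_DS <- c(AA = -24.0, AT = -23.9, TA = -16.9, CA = -12.9, GT = -17.3,
                  CT = -20.8, GA = -13.5, CG = -27.8, GC = -26.7, GG = -26.6)

#' Reverse complement of a DNA string
#' @param s Sequence over A/C/G/T/N (gaps not allowed).
#' @return The reverse complement, 5'->3'.
#' @export
reverse_complement <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  v <- comp[rev(strsplit(toupper(s), "", fixed = TRUE)[[1]])]
  if (anyNA(v)) stop("cannot reverse-complement: non-ACGTN character")
  paste(v, collapse = "")
}

#' Nearest-neighbor duplex melting temperature
#'
#' @param primer_sequence Gap-free A/C/G/T string, length >= 8.
#' @param params A `TmParams` (default: the calibrated set).
#' @return Melting temperature in degrees C (full precision; report to 1
#'   decimal).
#' @export
melting_temperature <- function(primer_sequence, params = tm_params()) {
  s <- toupper(primer_sequence)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(ch) < 8L) stop("primer too short for nearest-neighbor Tm")
  if (any(!ch %in% c("A", "C", "G", "T"))) {
    stop("ambiguous or illegal base in primer: ",
         paste(setdiff(unique(ch), c("A", "C", "G", "T")), collapse = ""))
  }
  din <- paste0(ch[-length(ch)], ch[-1])
  # stacks absent from the table equal their reverse complement's values
  dH <- dS <- numeric(length(din))
  for (i in seq_along(din)) {
    d <- din[i]
    if (!d %in% names(BRESLAUER_DH)) d <- reverse_complement(d)
    dH[i] <- BRESLAUER_DH[[d]]
    dS[i] <- BRESLAUER_DS[[d]]
  }
  R <- 1.987  # cal/(mol K)
  (sum(dH) + params$dH_init) * 1000 /
    (sum(dS) + params$dS_init + R * log(params$ct / 4)) -
    273.15 + 16.6 * log10(params$na)
}

#' Find species-diagnostic alignment columns
#'
#' A column is diagnostic for the target species when every target-species
#' row carries the same unambiguous base (A/C/G/T) and that base occurs in
#' no non-target row. Intraspecific polymorphism at a column disqualifies
#' it (fixation in the target is required). A gap or `N` among the
#' non-target states is treated as non-matching but flags the site as
#' lower-confidence; with `strict = TRUE` such sites are dropped.
#'
#' @param aln A `LabeledAlignment` containing >= 2 species.
#' @param target_species Species label to find diagnostics for.
#' @param strict Drop sites whose background contains gap or `N`.
#' @return data.frame sorted by column: `column` (0-based),
#'   `target_species`, `target_state`, `background_states` (collapsed
#'   string), `low_confidence`.
#' @export
find_diagnostic_sites <- function(aln, target_species, strict = FALSE) {
  if (length(unique(aln$species_of)) < 2L) {
    stop("need at least 2 species to define diagnostic sites")
  }
  m <- do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
  rownames(m) <- names(aln$rows)
  tgt <- aln$species_of[rownames(m)] == target_species
  if (!any(tgt)) stop("no rows for target species '", target_species, "'")
  out <- list()
  for (col in seq_len(ncol(m))) {
    ts <- unique(m[tgt, col])
    if (length(ts) != 1L || !ts %in% c("A", "C", "G", "T")) next
    bg <- unique(m[!tgt, col])
    if (ts %in% bg) next
    low <- any(bg %in% c("N", "-"))
    if (strict && low) next
    out[[length(out) + 1L]] <- data.frame(
      column = col - 1L, target_species = target_species,
      target_state = ts,
      background_states = paste(sort(bg), collapse = ""),
      low_confidence = low, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(column = integer(0), target_species = character(0),
                      target_state = character(0),
                      background_states = character(0),
                      low_confidence = logical(0)))
  }
  do.call(rbind, out)
}

#' Constraints for primer-pair design
#'
#' @param primer_len_min,primer_len_max Primer length bounds (nt).
#' @param tm_min,tm_max Acceptable primer Tm window (degrees C).
#' @param delta_tm_max Maximum Tm difference within a pair.
#' @param product_min,product_max Acceptable amplicon size range (bp).
#' @param size_target Preferred amplicon size; defaults to the midpoint of
#'   the product range. Used only for ranking.
#' @param annealing_offset Added to the minimum primer Tm of a pair to set
#'   its default annealing temperature.
#' @param tm_params `TmParams` used for all Tm computations.
#' @param interaction_threshold Minimum flagged 3'-complementary run.
#' @param strict_sites Drop lower-confidence diagnostic sites.
#' @param max_pairs Maximum number of validated pairs to return.
#' @return List of class `DesignConstraints`.
#' @export
design_constraints <- function(primer_len_min = 17L, primer_len_max = 27L,
                               tm_min = 52, tm_max = 68, delta_tm_max = 5,
                               product_min = 120L, product_max = 800L,
                               size_target = NULL, annealing_offset = 0,
                               tm_params = specimark::tm_params(),
                               interaction_threshold = 5L,
                               strict_sites = FALSE, max_pairs = 10L) {
  if (is.null(size_target)) size_target <- (product_min + product_max) / 2
  structure(as.list(environment()), class = "DesignConstraints")
}

# columns usable as primer footprint for a target species: every target
# row agrees and the shared state is A/C/G/T
clean_target_columns <- function(m, tgt) {
  apply(m[tgt, , drop = FALSE], 2, function(col) {
    u <- unique(col)
    length(u) == 1L && u %in% c("A", "C", "G", "T")
  })
}

#' Design species-specific primer pairs anchored on diagnostic sites
#'
#' Enumerates primer pairs in which at least one primer has its 3'
#' terminal base on a diagnostic site for the target species, subject to
#' length, Tm window, pair delta-Tm, and product-size constraints. The
#' amplicon length must be identical on every target-species sequence.
#' Every candidate is validated by in-silico PCR against all rows of the
#' training alignment: it must produce exactly one product on each target
#' row and none on any non-target row. Pairs are ranked by (i) number of
#' anchored primers (both > one), (ii) Tm closeness within the pair,
#' (iii) proximity of the product size to `size_target`.
#'
#' @param aln A `LabeledAlignment`.
#' @param target_species Species to design for.
#' @param constraints A `DesignConstraints`.
#' @return List of `MarkerPair` objects (possibly empty). When empty, the
#'   attribute `failure_tally` gives per-constraint rejection counts.
#' @export
design_primer_pairs <- function(aln, target_species,
                                constraints = design_constraints()) {
  cn <- constraints
  sites <- find_diagnostic_sites(aln, target_species,
                                 strict = cn$strict_sites)
  tally <- c(no_diagnostic_site = 0L, footprint = 0L, tm_window = 0L,
             delta_tm = 0L, product_size = 0L, unequal_target_size = 0L,
             insilico_specificity = 0L)
  if (nrow(sites) == 0L) {
    tally["no_diagnostic_site"] <- 1L
    return(structure(list(), failure_tally = tally))
  }
  m <- do.call(rbind, strsplit(unname(aln$rows), "", fixed = TRUE))
  rownames(m) <- names(aln$rows)
  tgt <- aln$species_of[rownames(m)] == target_species
  clean <- clean_target_columns(m, tgt)
  tstate <- m[which(tgt)[1], ]          # fixed target state on clean cols
  ncols <- ncol(m)

  seq_of_cols <- function(cols) paste(tstate[cols], collapse = "")

  # anchored forward candidates: 3' end on site column c1 (1-based)
  fwd_cands <- list()
  for (c1 in sites$column + 1L) {
    for (len in cn$primer_len_min:cn$primer_len_max) {
      lo <- c1 - len + 1L
      if (lo < 1L) next
      cols <- lo:c1
      if (!all(clean[cols])) { tally["footprint"] <- tally["footprint"] + 1L; next }
      sq <- seq_of_cols(cols)
      tm <- melting_temperature(sq, cn$tm_params)
      if (tm < cn$tm_min || tm > cn$tm_max) {
        tally["tm_window"] <- tally["tm_window"] + 1L; next
      }
      fwd_cands[[length(fwd_cands) + 1L]] <-
        list(span = c(lo, c1), sequence = sq, tm = tm, anchored = TRUE)
    }
  }
  # anchored reverse candidates: primer is revcomp of template span, 3'
  # end on the leftmost template column c0
  rev_cands <- list()
  for (c0 in sites$column + 1L) {
    for (len in cn$primer_len_min:cn$primer_len_max) {
      hi <- c0 + len - 1L
      if (hi > ncols) next
      cols <- c0:hi
      if (!all(clean[cols])) { tally["footprint"] <- tally["footprint"] + 1L; next }
      sq <- reverse_complement(seq_of_cols(cols))
      tm <- melting_temperature(sq, cn$tm_params)
      if (tm < cn$tm_min || tm > cn$tm_max) {
        tally["tm_window"] <- tally["tm_window"] + 1L; next
      }
      rev_cands[[length(rev_cands) + 1L]] <-
        list(span = c(c0, hi), sequence = sq, tm = tm, anchored = TRUE)
    }
  }
  # non-anchored partners are enumerated on demand around a given anchor;
  # 3' ends are stepped to keep the search tractable (primer placement
  # slack makes single-base resolution unnecessary)
  nonanchored <- function(sense, lo_col, hi_col, step = 3L) {
    out <- list()
    rng <- seq.int(lo_col, hi_col, by = step)
    for (end3 in rng) {
      for (len in cn$primer_len_min:cn$primer_len_max) {
        if (sense == "F") { lo <- end3 - len + 1L; if (lo < 1L) next; cols <- lo:end3 }
        else { hi <- end3 + len - 1L; if (hi > ncols) next; cols <- end3:hi }
        if (!all(clean[cols])) next
        sq <- seq_of_cols(cols)
        if (sense == "R") sq <- reverse_complement(sq)
        tm <- melting_temperature(sq, cn$tm_params)
        if (tm < cn$tm_min || tm > cn$tm_max) next
        out[[length(out) + 1L]] <- list(span = range(cols), sequence = sq,
                                        tm = tm, anchored = FALSE)
      }
    }
    out
  }

  # product length per target row: non-gap bases within the span; must be
  # identical across target rows (cumulative counts make this O(1))
  nongap_cum <- apply(m[tgt, , drop = FALSE] != "-", 1, cumsum)  # cols x rows
  product_sizes <- function(span) {
    lo <- if (span[1] > 1L) nongap_cum[span[1] - 1L, ] else 0L
    nongap_cum[span[2], ] - lo
  }

  candidates <- list()
  consider <- function(f, r) {
    if (r$span[1] <= f$span[2]) return()        # rev must lie downstream
    if (abs(f$tm - r$tm) > cn$delta_tm_max) {
      tally["delta_tm"] <<- tally["delta_tm"] + 1L; return()
    }
    sizes <- product_sizes(c(f$span[1], r$span[2]))
    if (length(unique(sizes)) != 1L) {
      tally["unequal_target_size"] <<- tally["unequal_target_size"] + 1L; return()
    }
    size <- sizes[1]
    if (size < cn$product_min || size > cn$product_max) {
      tally["product_size"] <<- tally["product_size"] + 1L; return()
    }
    candidates[[length(candidates) + 1L]] <<- list(f = f, r = r, size = size)
  }
  for (f in fwd_cands) for (r in rev_cands) consider(f, r)
  # when no doubly anchored pair satisfies the constraints, pair each
  # anchored primer with free partners on the other side
  if (!length(candidates)) {
    for (f in fwd_cands) {
      lo <- f$span[2] + cn$product_min - cn$primer_len_max
      hi <- min(ncols, f$span[1] + cn$product_max)
      if (lo <= hi) for (r in nonanchored("R", max(f$span[2] + 1L, lo), hi)) consider(f, r)
    }
    for (r in rev_cands) {
      lo <- max(1L, r$span[2] - cn$product_max)
      hi <- r$span[1] - cn$product_min + cn$primer_len_max
      if (lo <= hi) for (f in nonanchored("F", lo, min(hi, r$span[1] - 1L))) consider(f, r)
    }
  }

  if (!length(candidates)) return(structure(list(), failure_tally = tally))
  rank_key <- vapply(candidates, function(cd) {
    anchored <- cd$f$anchored + cd$r$anchored
    -anchored * 1e8 + abs(cd$f$tm - cd$r$tm) * 1e4 +
      abs(cd$size - cn$size_target)
  }, 0)
  candidates <- candidates[order(rank_key)]

  # in-silico validation against every row of the training alignment
  templates <- degap_rows(aln$rows)
  pairs <- list()
  short <- species_short(target_species)
  for (cd in candidates) {
    if (length(pairs) >= cn$max_pairs) break
    ok <- TRUE
    for (id in names(templates)) {
      preds <- predict_amplicons(cd$f$sequence, cd$r$sequence,
                                 templates[[id]])
      want <- if (aln$species_of[[id]] == target_species) 1L else 0L
      if (nrow(preds) != want) { ok <- FALSE; break }
    }
    if (!ok) { tally["insilico_specificity"] <- tally["insilico_specificity"] + 1L; next }
    k <- length(pairs) + 1L
    fwd <- primer_candidate(paste0(short, "F", k), "F", cd$f$sequence,
                            cd$f$span, cd$f$tm, cd$f$anchored)
    rev <- primer_candidate(paste0(short, "R", k), "R", cd$r$sequence,
                            cd$r$span, cd$r$tm, cd$r$anchored)
    pairs[[k]] <- marker_pair(fwd, rev, target_species, cd$size,
                              annealing_temp = round(min(cd$f$tm, cd$r$tm) +
                                                       cn$annealing_offset))
  }
  if (!length(pairs)) return(structure(list(), failure_tally = tally))
  pairs
}

species_short <- function(species) {
  gsub("[^A-Za-z0-9]", "", abbreviate(gsub("[ .]", "", species), 4))
}

degap_rows <- function(rows) {
  lapply(rows, function(s) gsub("-", "", s, fixed = TRUE))
}

#' Construct a PrimerCandidate
#' @param name Primer name.
#' @param sense "F" or "R".
#' @param sequence Primer sequence 5'->3' (gap-free).
#' @param span Alignment column span of the footprint (1-based inclusive).
#' @param tm_celsius Melting temperature.
#' @param anchored TRUE when the 3' terminal base sits on a diagnostic site.
#' @return List of class `PrimerCandidate`.
#' @export
primer_candidate <- function(name, sense, sequence, span = c(NA, NA),
                             tm_celsius = NA_real_, anchored = FALSE) {
  stopifnot(sense %in% c("F", "R"), !grepl("-", sequence, fixed = TRUE))
  structure(list(name = name, sense = sense, sequence = toupper(sequence),
                 span = span, tm_celsius = tm_celsius, anchored = anchored),
            class = "PrimerCandidate")
}

#' Construct a MarkerPair
#' @param forward,reverse `PrimerCandidate` objects.
#' @param target_species Species the marker identifies.
#' @param expected_size Product size (bp) on the target template.
#' @param annealing_temp Annealing temperature (degrees C).
#' @return List of class `MarkerPair` with a `name` built from the primers.
#' @export
marker_pair <- function(forward, reverse, target_species, expected_size,
                        annealing_temp = NA_real_) {
  structure(list(name = paste0(forward$name, "/", reverse$name),
                 forward = forward, reverse = reverse,
                 target_species = target_species,
                 expected_size = as.integer(expected_size),
                 annealing_temp = annealing_temp),
            class = "MarkerPair")
}

#' @export
print.MarkerPair <- function(x, ...) {
  cat(sprintf("MarkerPair %s -> %s: %d bp, Ta %.0f C (Tm %.1f/%.1f)\n",
              x$name, x$target_species, x$expected_size, x$annealing_temp,
              x$forward$tm_celsius, x$reverse$tm_celsius))
  invisible(x)
}

# longest antiparallel complementary run between p and q that includes
# either 3' terminus (p's last base or q's last base)
three_prime_run <- function(p, q) {
  a <- strsplit(toupper(p), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(q), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  np <- length(a); nq <- length(b)
  iscomp <- function(x, y) !is.na(comp[x]) && comp[[x]] == y
  best <- 0L
  # runs ending at p's 3' terminus: chain (..., (np, j))
  for (j in seq_len(nq)) {
    len <- 0L; i <- np; jj <- j
    while (i >= 1L && jj <= nq && iscomp(a[i], b[jj])) {
      len <- len + 1L; i <- i - 1L; jj <- jj + 1L
    }
    best <- max(best, len)
  }
  # runs ending at q's 3' terminus: chain (..., (i, nq))
  for (i in seq_len(np)) {
    len <- 0L; ii <- i; jj <- nq
    while (ii >= 1L && jj <= nq && iscomp(b[jj], a[ii])) {
      len <- len + 1L; ii <- ii - 1L; jj <- jj - 1L
    }
    best <- max(best, len)
  }
  best
}

hairpin_found <- function(p, min_stem = 4L, min_loop = 3L) {
  a <- strsplit(toupper(p), "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(a)
  for (i in seq_len(n)) {
    for (j in n:(i + 1)) {
      if (j - i - 1 < min_loop + 2 * (min_stem - 1)) break
      s <- 0L
      while (i + s <= n && j - s >= 1 && j - s - (i + s) - 1 >= min_loop &&
             !is.na(comp[a[i + s]]) && comp[[a[i + s]]] == a[j - s]) {
        s <- s + 1L
        if (s >= min_stem) return(TRUE)
      }
    }
  }
  FALSE
}

#' Screen primer-primer interactions and hairpins
#'
#' For every ordered pair of primers (including self-pairs) the longest
#' antiparallel complementary run that includes either 3' terminus is
#' computed; runs at or above `threshold` are flagged (3'-end dimers
#' prime extension). Hairpins are flagged for a self-complementary stem of
#' at least 4 bases enclosing a loop of at least 3.
#'
#' @param primers Named character vector of primer sequences, or a list of
#'   `PrimerCandidate`s.
#' @param threshold Minimum flagged run length.
#' @return List: `pairs` (data.frame primer_a, primer_b, run, flagged) and
#'   `hairpins` (data.frame primer, hairpin).
#' @export
screen_interactions <- function(primers, threshold = 5L) {
  if (is.list(primers) && all(vapply(primers, inherits, TRUE, "PrimerCandidate"))) {
    primers <- stats::setNames(vapply(primers, `[[`, "", "sequence"),
                               vapply(primers, `[[`, "", "name"))
  }
  ids <- names(primers)
  if (is.null(ids)) ids <- paste0("p", seq_along(primers))
  grid <- expand.grid(a = seq_along(primers), b = seq_along(primers))
  runs <- mapply(function(i, j) three_prime_run(primers[[i]], primers[[j]]),
                 grid$a, grid$b)
  pairs <- data.frame(primer_a = ids[grid$a], primer_b = ids[grid$b],
                      run = as.integer(runs),
                      flagged = runs >= threshold, stringsAsFactors = FALSE)
  hairpins <- data.frame(primer = ids,
                         hairpin = vapply(primers, hairpin_found, TRUE),
                         stringsAsFactors = FALSE)
  list(pairs = pairs, hairpins = hairpins)
}

#' Assemble multiplex PCR groups
#'
#' Markers are grouped by shared annealing temperature; within a group
#' every pairwise difference of expected product sizes must be at least
#' `min_separation` bp (so bands are separable on a gel) and no 3'
#' interaction between primers of different members may reach
#' `interaction_threshold`. Members are added greedily in input order;
#' violators are left ungrouped with the reason recorded.
#'
#' @param markers List of `MarkerPair`s.
#' @param min_separation Minimum pairwise product-size difference (bp).
#' @param interaction_threshold Flagged 3'-complementary run length.
#' @return List: `groups` (list of `MultiplexGroup`: `annealing_temp`,
#'   `members`, `sizes`, `min_size_separation`) and `ungrouped`
#'   (data.frame marker, reason).
#' @export
build_multiplex_groups <- function(markers, min_separation = 30L,
                                   interaction_threshold = 5L) {
  temps <- vapply(markers, `[[`, 0, "annealing_temp")
  names_ <- vapply(markers, `[[`, "", "name")
  groups <- list()
  ungrouped <- data.frame(marker = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  for (tt in unique(temps)) {
    member_idx <- integer(0)
    for (i in which(temps == tt)) {
      reason <- NULL
      for (j in member_idx) {
        sep <- abs(markers[[i]]$expected_size - markers[[j]]$expected_size)
        if (sep < min_separation) {
          reason <- sprintf("size separation %d < %d vs %s", sep,
                            min_separation, names_[j])
          break
        }
        pr <- c(fa = markers[[i]]$forward$sequence,
                ra = markers[[i]]$reverse$sequence,
                fb = markers[[j]]$forward$sequence,
                rb = markers[[j]]$reverse$sequence)
        sc <- screen_interactions(pr, threshold = interaction_threshold)
        cross <- sc$pairs[xor(sc$pairs$primer_a %in% c("fa", "ra"),
                              sc$pairs$primer_b %in% c("fa", "ra")), ]
        if (any(cross$flagged)) {
          reason <- sprintf("3' interaction with %s", names_[j])
          break
        }
      }
      if (is.null(reason)) {
        member_idx <- c(member_idx, i)
      } else {
        ungrouped <- rbind(ungrouped,
                           data.frame(marker = names_[i], reason = reason,
                                      stringsAsFactors = FALSE))
      }
    }
    if (length(member_idx)) {
      sizes <- vapply(markers[member_idx], `[[`, 0L, "expected_size")
      minsep <- if (length(sizes) > 1L) {
        min(stats::dist(sizes))
      } else NA_real_
      groups[[length(groups) + 1L]] <- structure(
        list(annealing_temp = tt, members = names_[member_idx],
             sizes = sizes, min_size_separation = minsep),
        class = "MultiplexGroup")
    }
  }
  list(groups = groups, ungrouped = ungrouped)
}
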