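#' Simulation parameters for labelled barcode sets
#'
#' Defaults emulate a panel of closely related chloroplast barcodes:
#' 7 species x 3 genotypes of 800 bp, between-species divergence in the
#' 0.008-0.024 substitutions/site regime (default expectation 0.016),
#' near-zero within-species divergence, transition/transversion rate
#' ratio kappa = 2, and a handful of guaranteed diagnostic sites per
#' species. Divergences are expected substitutions per site (branch
#' length), not percent identity. Indels are off by default (coding
#' chloroplast barcodes are nearly gap-free).
#'
#' @param n_species Number of species.
#' @param n_per_species Genotypes per species.
#' @param seq_length Sequence length (bp).
#' @param kappa Transition/transversion rate ratio.
#' @param d_inter Expected pairwise between-species divergence.
#' @param d_intra Expected pairwise within-species divergence.
#' @param n_planted_diagnostic Guaranteed diagnostic sites per species.
#' @param indel_rate Per-branch probability of a short indel (aligner
#'   testing only).
#' @param seed Mandatory integer seed.
#' @return List of class `SimParams`.
#' @export
sim_params <- function(n_species = 7L, n_per_species = 3L, seq_length = 800L,
                       kappa = 2.0, d_inter = 0.016, d_intra = 0.001,
                       n_planted_diagnostic = 3L, indel_rate = 0,
                       seed) {
  if (missing(seed)) stop("seed is mandatory for reproducibility")
  stopifnot(kappa > 0, d_inter >= 0, d_intra >= 0, d_intra <= d_inter,
            n_species >= 1, n_per_species >= 1, seq_length >= 1)
  structure(list(n_species = as.integer(n_species),
                 n_per_species = as.integer(n_per_species),
                 seq_length = as.integer(seq_length), kappa = kappa,
                 d_inter = d_inter, d_intra = d_intra,
                 n_planted_diagnostic = as.integer(n_planted_diagnostic),
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "SimParams")
}

# K2P substitution along a branch of length d (expected subs/site) with
# transition/transversion rate ratio kappa; closed-form site transition
# probabilities of the Kimura model. Codes 0=A,1=C,2=G,3=T.
k2p_evolve <- function(codes, d, kappa) {
  if (d <= 0) return(codes)
  beta <- 1 / (kappa + 2)          # total rate normalized to 1
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1         # each of the two transversion targets
  n <- length(codes)
  u <- stats::runif(n)
  fate <- ifelse(u < p_same, 0L, ifelse(u < p_same + p_ts, 1L, 2L))
  tv_pick <- stats::runif(n) < 0.5
  ts_partner <- c(2L, 3L, 0L, 1L)            # A<->G, C<->T
  tv1 <- c(1L, 0L, 1L, 0L)                   # A->C, C->A, G->C, T->A
  tv2 <- c(3L, 2L, 3L, 2L)                   # A->T, C->G, G->T, T->G
  out <- codes
  idx <- fate == 1L
  out[idx] <- ts_partner[codes[idx] + 1L]
  idx <- fate == 2L
  out[idx] <- ifelse(tv_pick[idx], tv1[codes[idx] + 1L],
                     tv2[codes[idx] + 1L])
  out
}

TRANSVERSION_PARTNER <- c(A = "C", C = "A", G = "T", T = "G")

#' Simulate a labelled multi-species barcode set
#'
#' A random ancestral sequence is evolved to each species ancestor along
#' a star tree with branches of `d_inter / 2` (so every between-species
#' pair has expected divergence `d_inter`) under a two-rate
#' (kappa-weighted) substitution process -- exactly the model the K2P
#' distance inverts. Individuals then evolve from their species ancestor
#' along branches of `d_intra / 2`. Afterwards `n_planted_diagnostic`
#' columns per species are forced to be fixed in the target species and
#' absent from every other individual; the registry records the planted
#' truth so tests can assert against it.
#'
#' @param params A `SimParams`.
#' @return List of class `SimulatedSet`: `sequences` (named vector, IDs
#'   `sp<i>_<j>`), `species_map` (data.frame), `tree` (true `phylo`),
#'   `registry` (data.frame species/column/base of planted sites),
#'   `params`.
#' @export
simulate_species_set <- function(params) {
  p <- params
  demand <- p$n_species * p$n_planted_diagnostic
  if (demand > p$seq_length) {
    stop("cannot honor ", demand, " planted diagnostic sites in ",
         p$seq_length, " bp")
  }
  if (p$d_inter >= 0.7) {
    stop("d_inter too high: substitution process saturates and planted ",
         "diagnostic sites cannot be guaranteed")
  }
  set.seed(p$seed)
  bases <- c("A", "C", "G", "T")
  root <- sample.int(4L, p$seq_length, replace = TRUE) - 1L
  species <- paste0("sp", seq_len(p$n_species))
  seqs <- list()
  for (s in seq_len(p$n_species)) {
    anc <- k2p_evolve(root, p$d_inter / 2, p$kappa)
    for (g in seq_len(p$n_per_species)) {
      id <- paste0(species[s], "_", g)
      codes <- k2p_evolve(anc, p$d_intra / 2, p$kappa)
      seqs[[id]] <- codes
    }
  }
  ids <- names(seqs)
  sp_of <- rep(species, each = p$n_per_species)
  names(sp_of) <- ids

  # plant diagnostic sites: distinct columns, fixed in target, absent in
  # every background individual
  registry <- data.frame(species = character(0), column = integer(0),
                         base = character(0), stringsAsFactors = FALSE)
  if (p$n_planted_diagnostic > 0L) {
    cols <- sample.int(p$seq_length, demand)
    k <- 0L
    for (s in species) {
      for (r in seq_len(p$n_planted_diagnostic)) {
        k <- k + 1L
        col <- cols[k]
        tgt_base_code <- seqs[[paste0(s, "_1")]][col]
        tgt_base <- bases[tgt_base_code + 1L]
        for (id in ids) {
          if (sp_of[[id]] == s) {
            seqs[[id]][col] <- tgt_base_code
          } else if (seqs[[id]][col] == tgt_base_code) {
            seqs[[id]][col] <-
              encode_seq(TRANSVERSION_PARTNER[[tgt_base]])
          }
        }
        registry <- rbind(registry, data.frame(
          species = s, column = col - 1L, base = tgt_base,
          stringsAsFactors = FALSE))
      }
    }
  }

  # optional short indels for aligner exercises: delete 1-3 bases per hit
  sequences <- vapply(seqs, function(codes) {
    paste(bases[codes + 1L], collapse = "")
  }, "")
  if (p$indel_rate > 0) {
    for (id in ids) {
      if (stats::runif(1) < p$indel_rate) {
        len <- sample(1:3, 1)
        pos <- sample.int(nchar(sequences[[id]]) - len - 1L, 1) + 1L
        sequences[[id]] <- paste0(substr(sequences[[id]], 1, pos - 1),
                                  substr(sequences[[id]], pos + len,
                                         nchar(sequences[[id]])))
      }
    }
  }

  nwk <- paste0("(", paste(vapply(species, function(s) {
    paste0("(", paste(paste0(s, "_", seq_len(p$n_per_species), ":",
                             p$d_intra / 2), collapse = ","), "):",
           p$d_inter / 2)
  }, ""), collapse = ","), ");")
  smap <- species_map(ids, sp_of[ids])
  structure(list(sequences = sequences, species_map = smap,
                 tree = ape::read.tree(text = nwk), registry = registry,
                 params = p),
            class = "SimulatedSet")
}

#' Quality-profile parameters for simulated reads
#'
#' Emulates single-pass chromatogram quality: low-quality ramps at both
#' ends, a high plateau, and random mid-read dips.
#'
#' @param mid_phred Plateau PHRED score.
#' @param end_phred Score at the outermost bases.
#' @param ramp_length Length of each end ramp (bases).
#' @param dip_rate Per-base probability of a low-quality dip in the
#'   plateau.
#' @return List of class `QualityProfile`.
#' @export
quality_profile <- function(mid_phred = 35L, end_phred = 10L,
                            ramp_length = 30L, dip_rate = 0.01) {
  stopifnot(mid_phred >= 0, mid_phred <= 93, end_phred >= 0,
            end_phred <= 93, ramp_length >= 0, dip_rate >= 0, dip_rate <= 1)
  structure(list(mid_phred = as.integer(mid_phred),
                 end_phred = as.integer(end_phred),
                 ramp_length = as.integer(ramp_length),
                 dip_rate = dip_rate),
            class = "QualityProfile")
}

# brute-force retained interval under the window rule; independent of the
# quality_control implementation (plain loop over all window positions)
brute_force_retained <- function(phred, qc = qc_params()) {
  n <- length(phred)
  w <- qc$window
  ok_starts <- integer(0)
  if (n >= w) {
    for (i in 1:(n - w + 1)) {
      if (all(phred[i:(i + w - 1)] > qc$window_min_phred)) {
        ok_starts <- c(ok_starts, i)
      }
    }
  }
  if (!length(ok_starts)) return(c(0L, 0L))
  c(ok_starts[1] - 1L, ok_starts[length(ok_starts)] + w - 1L)
}

#' Simulate per-base quality for a sequence
#'
#' @param sequence Template string (bases are kept as-is).
#' @param profile A `QualityProfile`.
#' @param seed Integer seed.
#' @param qc `QCParams` used to compute the generator-side truth.
#' @return List: `qseq` (a `QualitySequence`), `truth` (list with
#'   `retained` 0-based half-open interval, `masked_positions` 1-based,
#'   `n_fraction`, `status` -- all derived by a brute-force application of
#'   the same acceptance rules).
#' @export
simulate_quality <- function(sequence, profile = quality_profile(), seed,
                             qc = qc_params()) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  n <- nchar(sequence)
  ramp <- min(profile$ramp_length, floor(n / 2))
  phred <- rep(profile$mid_phred, n)
  if (ramp > 0) {
    up <- round(seq(profile$end_phred, profile$mid_phred, length.out = ramp))
    phred[seq_len(ramp)] <- up
    phred[n - seq_len(ramp) + 1L] <- up
  }
  dips <- which(stats::runif(n) < profile$dip_rate)
  if (length(dips)) phred[dips] <- sample(0:15, length(dips), replace = TRUE)
  phred <- pmax(0L, pmin(93L, as.integer(phred)))
  qseq <- quality_sequence("sim", sequence, phred)

  retained <- brute_force_retained(phred, qc)
  if (retained[2] > retained[1]) {
    idx <- (retained[1] + 1L):retained[2]
    masked <- idx[phred[idx] < qc$mask_below_phred]
    b <- strsplit(sequence, "")[[1]]
    n_count <- sum(b[idx] == "N" | idx %in% masked)
    nf <- n_count / length(idx)
    status <- if (nf > qc$max_n_fraction) "rejected" else "accepted"
  } else {
    masked <- integer(0); nf <- NA_real_; status <- "rejected"
  }
  list(qseq = qseq,
       truth = list(retained = retained, masked_positions = masked,
                    n_fraction = nf, status = status))
}

#' Copy a maternal chloroplast template into a hybrid sample
#'
#' Plastid inheritance is uniparental (maternal), so an interspecific
#' hybrid carries an essentially unchanged copy of its seed parent's
#' chloroplast barcode.
#'
#' @param maternal_sequence Ungapped template of the maternal lineage.
#' @param label Sample ID for the hybrid.
#' @return Named character vector of length 1.
#' @export
make_hybrid <- function(maternal_sequence, label = "hybrid") {
  stats::setNames(as.character(maternal_sequence), label)
}
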