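#' @useDynLib specimark, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_BASES <- c("A", "C", "G", "T", "N", "-")

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on ingest and RNA-style `U` is mapped to `T`.
#' Any character outside `A/C/G/T/N/-` aborts with the offending record
#' named, and duplicate record IDs are rejected: ingestion never silently
#' drops or rewrites records.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA IDs: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(s, "", fixed = TRUE)[[1]])
    length(setdiff(ch, VALID_BASES)) > 0
  }, logical(1))
  if (any(bad)) {
    offender <- ids[which(bad)[1]]
    ch <- setdiff(unique(strsplit(seqs[which(bad)[1]], "")[[1]]), VALID_BASES)
    stop("illegal character(s) ", paste(ch, collapse = ""),
         " in record '", offender, "'")
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read sequences with per-base PHRED quality
#'
#' Accepts either a Sanger-encoded (+33 offset) FASTQ file, or a FASTA file
#' paired with a `.qual` file of whitespace-separated integer scores. IDs
#' must match between the pair and score vectors must be the same length as
#' their sequences.
#'
#' @param seq_path FASTQ path, or FASTA path when `qual_path` is given.
#' @param qual_path Optional path to a `.qual` companion file.
#' @return List of `QualitySequence` objects (see [quality_sequence()]).
#' @export
read_quality <- function(seq_path, qual_path = NULL) {
  if (is.null(qual_path)) {
    fq <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(seq_path),
      warning = function(w) {
        if (grepl("metadata columns.*dropped", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    ids <- sub("\\s.*$", "", names(fq))
    scores <- as(Biostrings::quality(fq), "IntegerList")
    out <- lapply(seq_along(fq), function(i) {
      quality_sequence(ids[i], as.character(fq[[i]]), scores[[i]])
    })
  } else {
    seqs <- read_fasta(seq_path)
    quals <- read_qual_file(qual_path)
    if (!setequal(names(seqs), names(quals))) {
      only <- c(setdiff(names(seqs), names(quals)),
                setdiff(names(quals), names(seqs)))
      stop("IDs present in only one of sequence/quality files: ",
           paste(only, collapse = ", "))
    }
    out <- lapply(names(seqs), function(id) {
      if (nchar(seqs[[id]]) != length(quals[[id]])) {
        stop("sequence/quality length mismatch for record '", id, "': ",
             nchar(seqs[[id]]), " bases vs ", length(quals[[id]]), " scores")
      }
      quality_sequence(id, seqs[[id]], quals[[id]])
    })
  }
  names(out) <- vapply(out, `[[`, "", "sample_id")
  out
}

# .qual files share FASTA layout but carry integer scores
read_qual_file <- function(path) {
  if (!file.exists(path)) stop("qual file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no records in qual file: ", path)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  ends <- c(hdr[-1] - 1L, length(lines))
  quals <- lapply(seq_along(hdr), function(i) {
    body <- paste(lines[seq(hdr[i] + 1L, ends[i])], collapse = " ")
    as.integer(strsplit(trimws(body), "\\s+")[[1]])
  })
  names(quals) <- ids
  quals
}

#' Construct a QualitySequence
#'
#' Bases plus per-base PHRED scores and trimming/masking state. The
#' retained interval is 0-based half-open; `n_fraction` is the fraction of
#' `N` among retained bases.
#'
#' @param sample_id Record identifier.
#' @param bases Sequence string over `A/C/G/T/N` (uppercased, `U -> T`).
#' @param phred Integer vector of PHRED scores, one per base, each in 0-93.
#' @param trimmed_range 0-based half-open retained interval `c(start, end)`.
#' @return Object of class `QualitySequence`.
#' @export
quality_sequence <- function(sample_id, bases, phred,
                             trimmed_range = c(0L, nchar(bases))) {
  bases <- gsub("U", "T", toupper(bases), fixed = TRUE)
  phred <- as.integer(phred)
  if (nchar(bases) != length(phred)) {
    stop("record '", sample_id, "': ", nchar(bases), " bases but ",
         length(phred), " quality scores")
  }
  if (any(phred < 0L | phred > 93L)) {
    stop("record '", sample_id, "': PHRED scores must lie in [0, 93]")
  }
  stopifnot(trimmed_range[1] >= 0, trimmed_range[2] <= nchar(bases),
            trimmed_range[1] <= trimmed_range[2])
  structure(
    list(sample_id = sample_id, bases = bases, phred = phred,
         trimmed_range = as.integer(trimmed_range),
         n_fraction = retained_n_fraction(bases, trimmed_range),
         masked_count = 0L),
    class = "QualitySequence")
}

retained_n_fraction <- function(bases, trimmed_range) {
  len <- trimmed_range[2] - trimmed_range[1]
  if (len == 0L) return(0)
  kept <- substr(bases, trimmed_range[1] + 1L, trimmed_range[2])
  sum(strsplit(kept, "")[[1]] == "N") / len
}

#' @export
print.QualitySequence <- function(x, ...) {
  cat(sprintf("QualitySequence %s: %d bases, retained [%d, %d), %.1f%% N\n",
              x$sample_id, nchar(x$bases), x$trimmed_range[1],
              x$trimmed_range[2], 100 * x$n_fraction))
  invisible(x)
}

#' Read a sample-to-species map
#'
#' TSV with header columns `sample_id` and `species`; extra columns (e.g.
#' geographic origin) are carried along as metadata.
#'
#' @param path Path to the TSV file.
#' @return data.frame with at least `sample_id` and `species`.
#' @export
read_species_map <- function(path) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("species map missing or empty: ", path)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  if (!all(c("sample_id", "species") %in% names(df))) {
    stop("species map must have 'sample_id' and 'species' columns")
  }
  if (nrow(df) == 0L) stop("species map has no rows: ", path)
  species_map(df$sample_id, df$species, df)
}

#' Construct a species map from vectors
#'
#' @param sample_id Character vector of unique sample IDs.
#' @param species Character vector of species labels (nonempty).
#' @param extra Optional data.frame of additional metadata columns.
#' @return data.frame of class `species_map`.
#' @export
species_map <- function(sample_id, species, extra = NULL) {
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup)) stop("duplicate sample_id: ", paste(unique(dup), collapse = ", "))
  if (any(is.na(species) | !nzchar(trimws(species)))) {
    stop("empty species label for sample(s): ",
         paste(sample_id[is.na(species) | !nzchar(trimws(species))], collapse = ", "))
  }
  df <- data.frame(sample_id = sample_id, species = species,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    keep <- setdiff(names(extra), names(df))
    for (k in keep) df[[k]] <- extra[[k]]
  }
  class(df) <- c("species_map", "data.frame")
  df
}

species_lookup <- function(map) {
  stats::setNames(map$species, map$sample_id)
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths and integer bootstrap labels (when present as
#' `node.label`) are preserved.
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write a distance matrix as a square labelled TSV
#'
#' Distances are printed with 6 decimals; internal values are never
#' rounded, only the report is.
#'
#' @param dm A `DistanceMatrix` (see [distance_matrix()]).
#' @param path Output path.
#' @export
write_distance_tsv <- function(dm, path) {
  m <- format(round(dm$d, 6), nsmall = 6, trim = TRUE, scientific = FALSE)
  df <- data.frame(sample_id = dm$labels, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", dm$labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square distance TSV written by [write_distance_tsv()]
#' @param path Path to the TSV.
#' @param model Distance model label to attach ("K2P" or "p").
#' @return A `DistanceMatrix`.
#' @export
read_distance_tsv <- function(path, model = "K2P") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df$sample_id
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(labels, labels)
  structure(list(labels = labels, d = m, sites_used = NULL, model = model),
            class = "DistanceMatrix")
}

#' Write a marker report TSV
#'
#' One row per designed marker pair per primer, mirroring the columns of a
#' bench-facing primer table: name, sense, sequence 5'-3', melting
#' temperature, annealing temperature, expected product size, and target
#' species.
#'
#' @param markers List of `MarkerPair` objects (see [design_primer_pairs()]).
#' @param path Output path.
#' @export
write_marker_report <- function(markers, path) {
  rows <- do.call(rbind, lapply(markers, function(mp) {
    data.frame(
      name = c(mp$forward$name, mp$reverse$name),
      sense = c("F", "R"),
      sequence_5to3 = c(mp$forward$sequence, mp$reverse$sequence),
      melting_temp_c = round(c(mp$forward$tm_celsius, mp$reverse$tm_celsius), 1),
      annealing_temp_c = mp$annealing_temp,
      expected_size_bp = mp$expected_size,
      specificity = mp$target_species,
      stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
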