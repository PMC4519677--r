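#!/usr/bin/env Rscript
# Reproduce the published-panel analyses on the deposited barcode
# sequences. The sequences are NOT bundled (they live in GenBank under
# accessions KM068846-KM068887); download them yourself, e.g. with EDirect
# or from the NCBI web interface, as two plain FASTA files whose record
# IDs are the sample codes (Che1..Pur3), plus a sample->species TSV.
#
# Usage:
#   Rscript scripts/reproduce_accessions.R --matk matK.fasta \
#     --rbcl rbcL.fasta --species-map species.tsv --out results/accessions
#
# Outputs per locus: K2P distance matrix, per-species barcoding-gap table
# (min/max intra- and interspecific distances and the discrimination
# verdict), discrimination count, NJ tree with 1000 bootstrap replicates,
# and for matK an in-silico PCR check of the published species-specific
# primer pairs (expected bands: 396/364/315/332/644/476/619 bp on their
# targets, plus a 271 bp AChReF1 x AChR1 side product on A. cherimola)
# and the two multiplex groups at 65 and 69 degrees C.

suppressPackageStartupMessages({
  library(optparse)
  library(specimark)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--matk", type = "character"),
  make_option("--rbcl", type = "character", default = NULL),
  make_option("--species-map", type = "character", dest = "species_map"),
  make_option("--out", type = "character", default = "results/accessions"),
  make_option("--seed", type = "integer", default = 1L)
)))
if (is.null(opts$matk) || is.null(opts$species_map)) {
  stop("--matk and --species-map are required (see header for how to ",
       "obtain the sequences)")
}
dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
smap <- read_species_map(opts$species_map)

analyse_locus <- function(fasta, tag) {
  seqs <- read_fasta(fasta)
  aln <- progressive_msa(seqs, species_of = smap)
  dm <- distance_matrix(aln)
  write_distance_tsv(dm, file.path(opts$out, paste0(tag, "_distances.tsv")))
  gr <- gap_analysis(dm)
  write_gap_tsv(gr, file.path(opts$out, paste0(tag, "_gap.tsv")))
  cat(tag, "discriminated:", discrimination_count(gr), "of",
      nrow(gr), "species\n")
  tr <- bootstrap_support(aln, replicates = 1000, seed = opts$seed)
  write_newick(tr, file.path(opts$out, paste0(tag, "_nj.nwk")))
  aln
}

aln_matk <- analyse_locus(opts$matk, "matK")
if (!is.null(opts$rbcl)) analyse_locus(opts$rbcl, "rbcL")

# published matK marker panel
published <- list(
  list("AChF1", "GTATATGAATGTGAATCGGTATTC", "AChR1", "TTGACTCCTTACTGCGGAAT",
       "A. cherimola", 396L, 65),
  list("AChReF1", "GCTTCGGAATGATTTTCC", "AReR1", "CGCCTTAGCCAACGATT",
       "A. reticulata", 364L, 65),
  list("ASqF1", "CCATTTCCGTTTGTTCAAAC", "ASqR1", "GGTAAGATTTCCATTTCTTCATC",
       "A. squamosa", 315L, 69),
  list("AMuF1", "CATTTACGATCAACATCCTTTA", "AMuR1", "GAAGAATTTTGGCGTACACTTA",
       "A. muricata", 332L, 65),
  list("AMaF1", "ATACAAGATGCTCCCTCTTTG", "AMaR1", "TTAGCCAATGATCCAATCATT",
       "A. macroprophyllata", 644L, 69),
  list("AGlF1", "CGATCAACATCCTTTGGG", "AGlR1", "GCCGGCTTACTAATAGGGTT",
       "A. glabra", 476L, 69),
  list("APuF1", "TTCTTGTTCCTATATAATATTCATA", "APuR1",
       "GAGAAAGATTTCTGTATATGCGT", "A. purpurea", 619L, 61))
markers <- lapply(published, function(x) {
  marker_pair(primer_candidate(x[[1]], "F", x[[2]], tm_celsius =
                                 melting_temperature(x[[2]])),
              primer_candidate(x[[3]], "R", x[[4]], tm_celsius =
                                 melting_temperature(x[[4]])),
              x[[5]], x[[6]], annealing_temp = x[[7]])
})
templates <- vapply(aln_matk$rows, function(s) gsub("-", "", s), "")
smat <- specificity_matrix(markers, templates, aln_matk$species_of)
write_specificity_tsv(smat, file.path(opts$out, "matK_specificity.tsv"))
cat("specific markers:", sum(smat$specific), "of", length(markers), "\n")

# AChReF1 cross-binding side product on A. cherimola
che <- names(aln_matk$species_of)[aln_matk$species_of == "A. cherimola"][1]
if (!is.na(che)) {
  side <- predict_amplicons("GCTTCGGAATGATTTTCC", "TTGACTCCTTACTGCGGAAT",
                            templates[[che]])
  cat("AChReF1 x AChR1 on", che, "->",
      paste(side$product_length, collapse = ", "), "bp\n")
}

mg <- build_multiplex_groups(markers, min_separation = 30)
for (g in mg$groups) {
  cat(sprintf("multiplex @%g C: %s (sizes %s)\n", g$annealing_temp,
              paste(g$members, collapse = ", "),
              paste(g$sizes, collapse = "/")))
}
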