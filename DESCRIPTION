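Package: specimark
Title: DNA Barcoding Quality Control, Species Discrimination and
    Species-Specific Marker Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for DNA-barcode based species identification and
    the design of species-specific, multiplexable PCR markers. Implements
    PHRED-based sequence acceptance criteria (end trimming, low-quality
    masking, N-fraction rejection), native progressive multiple alignment,
    Kimura 2-parameter distances with pairwise deletion, barcoding-gap
    species discrimination, neighbor-joining trees with nonparametric
    bootstrap support, diagnostic-site discovery, nearest-neighbor melting
    temperature calculation, primer-interaction screening, multiplex group
    construction, and in-silico PCR validation including maternal-parent
    inference for interspecific hybrids. A sequence simulator with
    transition/transversion rate control generates labelled test data
    matching the statistical regime of closely related chloroplast
    barcodes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
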