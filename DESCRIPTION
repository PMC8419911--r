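Package: concatseq
Title: Variant Detection from Concatenated Enriched Amplicon Nanopore Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Somatic mutation detection from nanopore sequencing of
    allele-enriched amplicon concatemers. Simulates blocker-displacement
    enriched amplicon pools assembled into concatemer reads with a
    nanopore-like error model, deconcatenates reads by approximate junction
    matching, aligns monomer segments to panel amplicons, accumulates
    per-position pileups, computes variant read fraction (VRF) and delta-VRF
    statistics, applies a dual-gate calling rule (VRF and confidence-score
    thresholds), back-calculates original sample VAF from calibrated
    enrichment folds, and evaluates concordance and precision-recall against
    comparator call sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
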