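Package: rnaxtender
Title: Full-Length Extension and Characterization of Partial BLAST
    Matches for Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Post-processes nucleotide BLAST searches for non-coding
    RNAs. Partial high-scoring pairs (HSPs) are extended to predicted
    full-length subject sequences by coordinate arithmetic ("simple"), by
    anchored free-end-gap realignment of a padded subject window against
    the query ("locarna"-style), or by a model-scored combination of the
    two ("meta"). Extended matches are scored against a query model and
    classified as homologous, uncertain or not homologous by a bit-score
    rule. Secondary structures are predicted through a registry of method
    recipes combining constrained maximum-pairing folding, consensus
    structures from query-anchored alignments and suboptimal-structure
    selection, with adapters for external engines. A decoy-based
    synthetic benchmark measures extension accuracy and structure
    prediction quality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
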