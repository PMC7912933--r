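Package: metre
Title: Marker Capture and Mean Taxonomic Resolution Scoring for DNA Barcoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for evaluating the species-resolving power of DNA barcoding
    markers. Captures marker loci from genome assemblies by anchor-based exact
    matching against probe sequences, aligns the captured and reference sequences
    with a progressive affine-gap aligner (or an external aligner), computes raw
    p-distance matrices and within/between-species mean distances, and scores each
    marker with the Mean Taxonomic Resolution (MeTRe) index in both its
    actual-variability and fixed-threshold forms. Includes neighbor-joining trees,
    a Mantel permutation test, a cophenetic tree-agreement score, and a synthetic
    fixture generator with exact, known divergences for validation.
License: MIT + file LICENSE
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
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
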