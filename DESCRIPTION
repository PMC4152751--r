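Package: mirnovel
Title: Novel microRNA Discovery and Biomarker Evaluation for Serum Small
    RNA Sequencing
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of serum small RNA sequencing libraries
    for novel microRNA discovery: adapter and quality cleaning of raw
    reads, collapsing to unique tags, exact genome mapping, hierarchical
    annotation against known non-coding RNA classes, MIREAP-style hairpin
    candidate calling backed by a built-in nearest-neighbour minimum free
    energy folding engine, triplet structure-sequence feature filtering of
    pseudo precursors with a maximum-margin classifier, known-miRNA and
    replicate-consistency filtering, reads-per-million normalization with
    pseudocount rules, Mann-Whitney differential expression, and qPCR
    2^-ddCt / ROC biomarker evaluation. Includes a synthetic-data
    generator that plants known, novel and pseudo hairpins in a toy
    genome and simulates replicated read libraries and Ct tables against
    a truth manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    e1071,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
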