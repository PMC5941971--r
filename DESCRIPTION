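Package: ptrcensus
Title: Cataloging Polymorphic Tandem Repeats Across Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a catalog of polymorphic tandem repeats (PTR) by
    comparing assembled genomes against a reference. Candidate tandem
    repeats are consolidated from multiple detectors (or found with the
    built-in mismatch-tolerant scanner), located on target assemblies by
    uniquely anchoring their 250 bp flanking regions with local
    alignment, and scored for repeat-unit expansion or contraction with
    an evolutionary-distance test pair on a unit-cost dynamic program.
    Measurements are graded high/medium/low by the mutual consistency of
    the two alignments, filtered, deduplicated, and emitted as a
    tab-separated catalog together with comparison utilities (interval
    Jaccard matching, stratified PTR/TR ratios with bootstrap confidence
    intervals, delta histograms, windowed SNP-density correlation) and a
    seeded synthetic-fixture generator with planted ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
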