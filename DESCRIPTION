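Package: synoclone
Title: Clonal and Transcriptional Analysis of T Cells Across Blood and
    Synovial Fluid
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for paired single-cell transcriptome and T-cell receptor
    (TCR) repertoire analysis of sorted T-cell populations sampled from two
    tissue compartments (peripheral blood and synovial fluid).  Implements
    cell-level quality control, hashtag-oligo demultiplexing with a
    negative-binomial background threshold, clonotype calling from paired
    alpha/beta CDR3 nucleotide sequences, per-clone compartment enrichment
    testing (two-sided Fisher's exact test with Benjamini-Hochberg
    correction), clonal fate mapping across transcriptional clusters,
    Wilcoxon rank-sum differential expression, gene-module scoring with
    expression-matched controls, and a truth-labelled synthetic data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
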