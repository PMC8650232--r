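Package: splicelink
Title: Alternative Splicing Event Analysis and Splicing-to-Expression
    Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and classifies alternative-splicing events from
    splice-junction read counts, quantifies per-sample splicing ratios
    and tests group differences, performs trimmed-mean-of-M-values
    normalisation and negative-binomial exact-test differential
    expression, scans promoter windows with position weight matrices for
    motif over-representation, matches enriched motifs to
    splicing-regulated transcription factors, and correlates transcription
    factor splicing ratios with target gene expression to build a
    regulatory network. Ships a fully deterministic synthetic-data
    generator (gene models, junction and gene counts, promoters with
    planted motifs) with a machine-readable truth table for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
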