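Package: barnyard
Title: Benchmarking Toolkit for Barnyard Single-Cell RNA-seq Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for quality benchmarking of high-throughput single-cell
    RNA-seq data using two-species ("barnyard") cell-line mixtures. Implements
    UMI error correction by single-base collapse, kernel-density-based library
    depth normalization, barcode-rank knee/inflection cell calling, correlation
    classification of cells against bulk RNA-seq signatures, cross-species
    multiplet-rate estimation with an occupancy adjustment factor, exponential
    dropout modeling with the GD50 detection statistic, pseudo-bulk concordance
    curves, and differential-expression recall/precision scoring with a
    two-part hurdle test. A synthetic barnyard-data generator with full ground
    truth makes every stage testable without sequencing data.
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
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
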