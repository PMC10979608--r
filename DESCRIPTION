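Package: scpbench
Title: Benchmarking Single-Cell RNA-Seq Library Preparation Protocols
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative comparison of single-cell RNA-seq libraries prepared
    under different sample-processing protocols (e.g. fresh versus fixed
    tissue). Implements exact read downsampling without replacement and
    saturation curves with linear-fit confidence-interval comparison, per-cell
    complexity regression, gene-accumulation curves, quality-control filtering
    including a two-pass mitochondrial scheme for colon tissue, log
    normalization and highly-variable-gene overlap, pseudo-bulk Pearson
    correlation with population-size rules, rank-sum differential expression
    with log-fold-change, FDR and presence filters, descriptive cell-type
    composition comparison with bootstrap intervals, rank-based (UCell-style)
    stress-signature scoring, and pre-ranked gene-set enrichment with a
    gene-permutation null. A molecule-level synthetic data generator with
    known ground truth supports calibration and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
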