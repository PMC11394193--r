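Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR Normalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation pipeline for candidate RT-qPCR reference
    (housekeeping) genes. Screens candidates from an RNA-seq FPKM matrix by
    expression level and coefficient of variation, transforms quantification
    cycles (Cq) to relative quantities, and ranks gene stability with four
    algorithms: geNorm pairwise-variation M values with the V(n/n+1)
    optimal-gene-number rule, a NormFinder-style intra-/intergroup variance
    decomposition, BestKeeper descriptive statistics on raw Cq, and the
    comparative delta-Ct method. Per-method ranks are aggregated by geometric
    mean into a comprehensive consensus ranking, and chosen references are
    validated by delta-delta-Ct fold changes of target genes with one-way
    ANOVA group comparison. A seeded synthetic-data generator produces Cq
    panels, FPKM matrices and dilution series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
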