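Package: gblupr
Title: Genomic Relationship Matrices, REML Mixed Models and Polygenic
    Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Single-node toolkit for quantitative-genetic analysis of
    biallelic SNP data: reading and writing PLINK binary genotypes,
    genomic relationship matrices (GRM) with GCTA-compatible binary
    storage, restricted maximum likelihood (REML) estimation of additive
    variance components by average-information updates or by an exact
    eigen-rotation fast path, best linear unbiased prediction (BLUP) of
    individual genetic values and SNP effects, polygenic scoring of new
    cohorts, principal component analysis of the GRM, single-marker
    association scans, and a simulation framework for additive traits
    with configurable heritability and QTN architecture, including
    train/validation prediction-accuracy experiments.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
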