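Package: gsbench
Title: Genomic Selection Benchmarking with Gain-Guided Marker Panel Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable pipeline for genotype-to-phenotype prediction studies:
    synthetic genotype and phenotype simulation with linkage-disequilibrium
    blocks and tunable heritability, VCF import and preprocessing filters
    (line and SNP missingness, minor allele frequency, sequential thinning),
    invertible one-hot encoding of diploid genotype calls, benchmarking of
    four model families (XGBoost, random forest, and in-package convolutional
    and dense neural networks) under k-fold cross-validation, gain-based
    feature ranking clustered into Regions of Importance, a single-marker
    association scan with principal-component covariates, and region-guided
    input reduction with re-benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    xgboost,
    randomForest,
    lhs,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
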