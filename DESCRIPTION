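Package: sepstab
Title: Stability-Driven Biomarker Discovery for Complicated Sepsis Course
Version: 0.1.0
Authors@R:
    person("Sepstab", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for discovering stable transcriptomic
    biomarkers of a complicated sepsis course from peripheral-blood gene
    expression. Provides matrix-level quantile normalization, surrogate
    variable diagnostics and empirical-Bayes batch adjustment, moderated-t
    differential expression with Benjamini-Hochberg control, six
    class-imbalance resampling schemes, pooled multi-method feature
    selection with recursive feature elimination inside repeated
    stratified cross-validation, per-feature normalized stability scores,
    threshold-swept classification metrics, Kolmogorov-Smirnov
    distributional validation, and a train-on-derivation /
    test-on-external-cohort protocol, together with a synthetic-cohort
    generator that emulates the statistical structure of the target data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    FNN,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
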