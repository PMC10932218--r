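Package: qpcrstab
Title: Reference-Gene Stability Evaluation and Relative Quantification for RT-qPCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating candidate reference (housekeeping) genes in
    RT-qPCR experiments with grouped samples, such as developmental time
    courses. Implements four expression-stability estimators (a model-based
    variance-components score in the NormFinder family, mean and standard
    deviation of raw Ct, coefficient of variation of linearized expression,
    and pairwise delta-Ct), per-method and aggregate stability ranking,
    multi-reference geometric-mean delta-delta-Ct normalization against a
    calibrator group, concordance of qPCR and RNA-seq fold-change profiles,
    and group-comparison statistics including the Brown-Forsythe modified-F
    one-way ANOVA for unequal variances. A synthetic Ct-data generator with
    known ground truth supports parameter-recovery testing of every
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
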