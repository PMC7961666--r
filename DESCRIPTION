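Package: iolstack
Title: Intraocular Lens Power Formulas, Constant Optimization and Stacked
    Machine-Learning Prediction of Postoperative Refraction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Thin-lens vergence implementations of the SRK/T, Holladay 1,
    Hoffer Q and Haigis intraocular lens (IOL) power calculation formulas,
    with forward (predicted refraction) and inverse (power for a target
    refraction) solvers; data-driven per-lens constant optimization by
    zero-mean-error root finding and by back-solved effective lens position
    regression; a synthetic biometry cohort generator with a known optical
    ground truth; a stacked machine-learning predictor (support vector,
    random forest, gradient boosting, and averaged neural-network
    regression) that consumes a conventional formula's predicted refraction
    as a feature; and the paired statistical evaluation battery used to
    compare prediction methods (Friedman, Wilcoxon/t with Bonferroni
    correction, chi-squared proportion tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    e1071,
    ranger,
    xgboost,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
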