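Package: ewlpredict
Title: Linear and Neural Correlation Models for Predicting Excess Weight
    Loss After Adjustable Gastric Banding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Re-implements, as a tested analysis pipeline, an
    outcome-prediction analysis of laparoscopic adjustable gastric banding
    (LAGB) in obese women: exhaustive best-subset linear regression of
    two-year excess weight loss (EWL) on age and MMPI-2 psychometric T
    scores with collinearity and residual diagnostics; a dual
    multi-layer-perceptron correlation-maximization model (a nonlinear
    canonical-correlation construction) trained by penalty-constrained
    multi-start quasi-Newton optimization with validation-based run
    rejection; quartile classification, ROC/AUC analysis with
    closest-to-corner cutoff selection, and repeated k-fold
    cross-validation summarized by averaged confusion matrices; and
    chi-square comparison of categorized T-score distributions against a
    normative population.  A synthetic cohort generator with plantable
    (non)linear outcome structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
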