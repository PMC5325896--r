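Package: tircval
Title: Validation Toolkit for the Thoracic Injury Rule-Out Criteria (TIRC)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Thoracic Injury Rule-out Criteria (TIRC), a
    checklist-style clinical decision rule for selecting blunt multiple
    trauma patients who need a chest radiograph, together with the full
    diagnostic-accuracy validation pipeline used to assess such rules:
    confusion table, sensitivity, specificity, predictive values and
    likelihood ratios with confidence intervals (continuity-corrected
    Wilson, Wilson, Clopper-Pearson; log-method for likelihood ratios),
    empirical ROC curve and trapezoidal AUC, Brier score with Murphy
    decomposition, and weighted calibration-line fitting.  A synthetic
    cohort generator reproduces the published cohort structure, either as
    a deterministic fixture that satisfies an exact rule-versus-outcome
    cross-classification or as a seeded stochastic sampler matching the
    published marginal frequencies in expectation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
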