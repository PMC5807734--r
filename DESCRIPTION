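Package: jfrail
Title: Joint Frailty Models for Recurrent Events and Death with Dynamic
    Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prepares long-format event-history cohorts of cancer
    recurrences (locoregional recurrence, metastasis, second primary)
    and death, fits a joint gamma-frailty model in which a shared
    subject-level frailty multiplies the recurrence intensity and, raised
    to a power, the death hazard, and derives dynamic individual
    predictions of death over a window given the recurrence history.
    Marginal likelihoods are integrated over the frailty with generalized
    Gauss-Laguerre quadrature; prediction accuracy is assessed with an
    inverse-probability-of-censoring-weighted Brier score.  A cohort
    simulator implementing the model's data-generating process supports
    calibration experiments and end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    pracma,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
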