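Package: kidneybenefit
Title: Predicting Individual Kidney-Protection Benefit of SGLT2 Inhibitors
    in Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating and validating individual-level absolute
    kidney-protection benefit of SGLT2 inhibitor treatment in adults with
    type 2 diabetes, preserved eGFR and normal-to-low albuminuria. Implements
    a four-step target-trial emulation pipeline: (1) overlap-weighted doubly
    robust Cox proportional hazards estimation of the relative treatment
    effect, with albuminuria and restricted-cubic-spline risk-score
    interaction tests; (2) calibration, Brier score and C statistic
    assessment of a proportional-hazards kidney-disease-progression risk
    score; (3) predicted absolute risk reductions (pARR) and their
    calibration against counterfactual absolute risk reductions; and
    (4) decision-curve comparison of pARR-threshold and albuminuria-threshold
    treatment strategies. Includes a seeded synthetic electronic-health-record
    cohort generator with confounded treatment assignment, competing
    censoring, crossover, and configurable missingness, plus chained-equation
    multiple imputation with Rubin's-rules pooling.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    nnet,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
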