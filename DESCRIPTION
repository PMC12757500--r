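Package: ckdfair
Title: Fairness Auditing of Pooled and Race-Specific Risk Models for
    Chronic Kidney Disease Progression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates race-structured chronic kidney disease (CKD)
    cohorts with correlated clinical covariates, eGFR trajectories and a
    composite five-year progression endpoint; trains race-blind (pooled)
    and race-specific (modular) feed-forward neural-network risk models
    under stratified cross-validation with class-imbalance handling; and
    audits the resulting out-of-fold predictions with discrimination,
    calibration (calibration-in-the-large, slope, expected calibration
    error, reliability bins), group-fairness (statistical parity,
    equalized odds, predictive parity) and decision-curve net-benefit
    metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
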