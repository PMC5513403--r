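Package: adpkdval
Title: External Validation of Kidney-Volume-Based eGFR Prediction Models in
    ADPKD
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to externally validate, apply and update clinical
    prediction models of kidney function decline in autosomal dominant
    polycystic kidney disease (ADPKD). Implements Mayo-style 1A-1E risk
    subclassification from age and height-adjusted total kidney volume
    (HtTKV), the CKD-EPI creatinine equation, a linear mixed-effects model
    for eGFR at t years of follow-up with subject-specific slopes, partial
    coefficient updating against frozen external coefficients via
    offset-likelihood refits, multiple imputation of missing kidney volumes
    with a multivariate-normal data-augmentation MCMC sampler and Rubin's
    pooling rules, and a full agreement/discrimination metric suite
    (Bland-Altman bias and 95% limits of agreement, P30 accuracy, R-squared,
    AIC, continuous ranked probability score) with patient-level k-fold
    cross-validation. A seeded synthetic longitudinal cohort generator
    emulating published ADPKD cohort structure makes the whole pipeline
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
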