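Package: landmarker
Title: Dynamic Prediction of Survival from Longitudinal Registry Data by Landmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic prediction of survival from longitudinal
    patient-registry data using the landmarking approach. Provides a
    synthetic-registry generator with a known generative hazard (so every
    stage is testable against ground truth), construction and stacking of
    landmark datasets with last-observation-carried-forward covariate
    summaries, a stratified Cox proportional-hazards engine with robust
    clustered variance, Breslow baseline hazards and landmark- or
    time-interaction terms, six supermodel variants, a multivariate linear
    mixed model for two-stage landmarking, and an evaluation suite with
    truncated concordance, inverse-probability-of-censoring-weighted Brier
    scores, calibration tables and Monte-Carlo cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    survival,
    tools,
    tibble,
    tidyr,
    utils
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
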