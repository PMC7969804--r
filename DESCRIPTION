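Package: oculoseason
Title: Oculomotor Biomarkers of Season-Long Head-Impact Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for longitudinal oculomotor
    monitoring of contact-sport athletes. Builds the three standard
    eye-tracking task schedules (smooth pursuit, visually guided saccade,
    anti-saccade), simulates 1 kHz gaze traces with ground-truth event logs
    and a synthetic longitudinal cohort, detects saccades and fixations,
    extracts an oculomotor feature battery (reaction time, landing error,
    main-sequence slope, Q-ratio, pursuit gain, catch-up and premature
    saccades, anti-saccade errors, fixation dispersion), aggregates ImPACT
    composites into an oriented first principal component (PC-ImPACT), and
    predicts optic nerve sheath diameter (ONSD) or PC-ImPACT from feature
    principal components with maximum-likelihood random-intercept linear
    mixed-effects models under nested leave-one-session-out
    cross-validation, in raw and baseline-subtracted (subtractive
    normalized) variants, with fixed-effects-only baselines, prediction
    metrics, feature-importance weighting, and season-level descriptive
    statistics (per-session t-tests, Cohen's d, correlation panels,
    linear-vs-quadratic fits with Cook's D screening).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
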