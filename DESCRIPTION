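Package: ecgsurv
Title: Dynamic Ventricular Arrhythmia Risk Prediction from Longitudinal ECGs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dynamic risk prediction of malignant ventricular
    arrhythmias in implantable cardioverter-defibrillator carriers from
    longitudinally collected six-lead electrocardiograms. Raw limb-lead
    signals are filtered, beat-averaged into per-lead mean-beat templates and
    compressed to a 16-variable latent representation by a beta-variational
    autoencoder; latent trajectories are combined with static baseline
    covariates in 90-day person-period intervals and fed to a
    Poisson-splitting survival forest with Bayes-smoothed leaf hazard rates,
    yielding updated piecewise-constant hazard predictions. Includes a
    seed-reproducible synthetic cohort generator (Gaussian-sum beat model,
    morphology drift, piecewise-constant event hazards), time-dependent ROC
    and decile calibration evaluation, patient-level bootstrap, permutation
    feature importance, latent factor traversal, and a manifest-based
    pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    rlang,
    signal,
    stats,
    survival,
    tibble,
    tools,
    utils,
    yaml,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
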