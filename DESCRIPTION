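Package: semgtorque
Title: Isometric Wrist Torque Estimation from Surface Electromyography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Pipeline for estimating isometric wrist flexion/extension torque
    from multi-channel surface electromyography (SEMG). Conditions raw SEMG
    into normalized activation envelopes (zero-phase Butterworth filtering,
    rectification, per-channel normalization, decimation), fits six torque
    estimators (a physiological neuromusculoskeletal activation-dynamics
    model calibrated by a genetic algorithm, ordinary least squares,
    l1-regularized least squares, epsilon-SVR, a two-hidden-layer neural
    network, and a receptive-field locally weighted regressor), and
    orchestrates channel-subset, training-size, cross-session and arm-posture
    experiments with NRMSE and adjusted R-squared reporting. Includes a
    seeded synthetic SEMG/torque cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
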