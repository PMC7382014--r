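Package: facetremor
Title: Facial-Landmark Trajectory Analysis for Parkinson Disease Screening
Version: 0.1.0
Authors@R: person("facetremor", "developers", email = "facetremor@example.org",
    role = c("aut", "cre"))
Description: Tools for screening Parkinson disease from facial-landmark video
    trajectories. Normalizes 106-point landmark sequences into a face-anchored
    relative coordinate system, extracts per-keypoint expression-amplitude and
    positional-jitter (RAP/PPQ5/DDP) features, screens features by two-group
    significance testing, compresses them with the LASSO, classifies records
    with classical machine learning (logistic regression, support vector
    machine, decision tree, random forest) and a first-difference LSTM
    sequence model, and ships a synthetic landmark-cohort generator so the
    whole pipeline is testable without clinical video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
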