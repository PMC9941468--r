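Package: presacc
Title: Presaccadic Visual Acuity Pipelines: Adaptive Titration, Saccade
    Detection, and Permutation Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for presaccadic visual-acuity
    experiments. Provides a Bayesian adaptive staircase engine for
    estimating spatial-frequency thresholds in two-alternative
    forced-choice tasks, maximum-likelihood psychometric refitting of
    binned accuracy data, velocity-threshold saccade detection with
    trial-gating rules, and permutation-based repeated-measures
    statistics with false-discovery-rate correction and
    within-subject (Cousineau) error bars. A synthetic-observer module
    generates full experimental sessions -- trial schedules, responses,
    and millisecond gaze traces -- with performance-field asymmetries
    (horizontal-vertical anisotropy and vertical-meridian asymmetry)
    and presaccadic benefits and costs, so every pipeline stage can be
    validated end-to-end by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readr,
    optparse
Config/testthat/edition: 3
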