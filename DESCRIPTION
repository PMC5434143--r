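Package: attnalloc
Title: Inferring Covert Attention Allocation from Forced-Choice Accuracy and Gaze
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for a cognitive two-armed-bandit attention task in which two
    brief digit rows compete for covert attention. Implements the linear
    forward model linking attention allocation, guessing and cued-trial
    accuracy to forced-choice performance, its closed-form inversion into
    per-subject allocation and guess-rate estimates, a velocity-threshold
    fixation detector with area-of-interest (AOI) classification, per-AOI
    conditional-accuracy and fixation-distribution analyses with tie-corrected
    Spearman rank correlations, distance-accuracy curve fits, and
    probability-matching line fits. A synthetic-data generator emulates the
    full experiment (display geometry, stimulus screens, staircase exposure
    calibration, 500 Hz gaze streams) so every analysis stage is testable
    end to end.
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
    broom,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
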