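Package: sleepverse
Title: Multiverse Analysis of Smartphone-Sensed Sleep and Mood
Version: 0.1.0
Authors@R:
    person("Sleepverse", "Developers", email = "maintainers@sleepverse.org",
           role = c("aut", "cre"))
Description: A tested pipeline from raw smartphone sensor event streams
    (accelerometer, charging state, ambient light, activity recognition,
    screen state, Wi-Fi) to per-night sleep/wake window grids, derived
    sleep features (bed time, wake-up time, sleep duration, interruptions,
    prior-day activity), outlier handling, and single-predictor models of
    subjective sleep quality, negative affect and depression.  The full
    12,600-combination multiverse of sensor thresholds, features, outcomes,
    model families, outlier strategies and run-length parameters is
    enumerated and evaluated with a hold-out workflow and one-standard-error
    model selection.  A synthetic-data generator with known ground-truth
    sleep schedules makes every stage testable by construction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    lme4,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
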