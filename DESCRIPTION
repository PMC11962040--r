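Package: oxmove
Title: Seabird Foraging Behaviour and Oxidative Stress from GPS Biologging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to derive central-place foraging metrics from seabird GPS
    trajectories and relate them to plasma oxidative stress. Provides speed
    filtering and regular-grid resampling of tracks, colony-distance trip
    segmentation, takeoff counting and land-utilization percentages, a
    three-state hidden Markov model (gamma step lengths, von Mises turning
    angles) fitted by EM and decoded by Viterbi, paired d-ROMs/BAP change
    computation, interval-censored (Tobit) Gaussian regression at assay
    detection limits, iterative variance-inflation-factor predictor pruning,
    and Bayesian Gaussian regression with 95% credible-interval sign calls.
    Includes a synthetic-data generator with known ground truth and an
    end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival,
    car,
    mgcv,
    geosphere,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
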