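Package: stillframe
Title: Semi-Automated Freezing and Motor-Activity Scoring from Fixed-Camera Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores freezing behavior and motor activity of a single animal in
    fixed-camera video by unsupervised clustering of frame-to-frame similarity
    scores. Consecutive grayscale frames are compared by their squared Pearson
    correlation; the resulting similarity trace is denoised (outlier
    substitution plus median filtering) and clustered with a three-component
    one-dimensional Gaussian mixture fit by expectation-maximization with
    random restarts. Posterior probabilities of the freezing and motion
    components yield freezing bouts (minimum three seconds) and a summed
    motor-activity index, with a manual point-estimate override for degenerate
    sessions. Includes rater-validation tools (Cohen's kappa, round-robin
    interrater reliability, sensitivity/specificity against rater consensus),
    session-level behavioral statistics (split-half tests, per-minute freezing
    probabilities, log-transformed correlations), and a ground-truthed
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    mclust,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
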