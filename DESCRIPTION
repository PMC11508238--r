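Package: icucount
Title: People Counting and Occupancy Analysis for ICU Room Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Counting-by-detection pipeline for ambient monitoring of intensive
    care unit (ICU) rooms. Provides a seeded simulator of room scenes and
    detector noise, three counting methods (single-frame, centered multi-frame
    averaging, and tracking-to-count with Kalman-filtered trajectories,
    appearance re-identification, bipartite assignment and trajectory category
    voting), detection metrics (IoU, 101-point average precision, mAP over IoU
    thresholds 0.50-0.95), counting metrics (accuracy, MAE, MRE, MSE, RMSE),
    and a segment-based clinician/visitor occupancy-duration analysis around
    delirium assessments (CAM-ICU / CAM-ICU-7).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
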