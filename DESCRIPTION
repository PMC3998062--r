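Package: iarat
Title: Instrumented Action Research Arm Test from a Wrist-Worn Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative upper-limb assessment with a single
    wrist-mounted inertial measurement unit recorded during the Action
    Research Arm Test (ARAT). Provides a documented CSV dialect for
    tri-axial accelerometer/gyroscope recordings with per-sample
    orientation, zero-lag Butterworth preprocessing, gravity-free
    global-frame acceleration, threshold-based segmentation of each task
    into sub-movements (reaching, manipulation, transport, release,
    return), duration and log-normalized jerk smoothness metrics,
    z-scores against a control cohort, clinical-score utilities (Nine
    Hole Peg Test conversion, UPGMA impairment clustering, cohort
    summaries), a nonparametric statistics battery (Mann-Whitney,
    Kruskal-Wallis, Friedman, Holm adjustment, Spearman), and a synthetic
    movement simulator with ground truth for end-to-end validation.
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
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
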