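Package: gazeqc
Title: Quality Assessment for Screen-Based Eye-Tracking Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for verifying the calibration quality of screen-based
    eye-tracking recordings. Reads tab-separated gaze exports, classifies
    fixations with a velocity-threshold (I-VT) filter, and computes
    per-trial spatial accuracy and precision (per-axis standard deviation
    and sample-to-sample RMS) in degrees of visual angle from a
    five-target verification procedure. Applies trial-level outlier and
    participant-level inclusion rules, compares verification runs and
    participant groups with nonparametric tests, and ships a synthetic
    300 Hz gaze simulator with analytic ground truth so the whole
    pipeline can be exercised without an eye tracker.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
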