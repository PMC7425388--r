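Package: nptfrp
Title: Eye-Tracking Metrics and Presaccadic EEG Potentials for the Noise
    Pareidolia Test
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of coregistered eye-tracking and EEG
    sessions of the computerised noise pareidolia test (NPT): I-VT gaze
    event detection, area-of-interest dwell metrics over early and late
    visual-search windows, signal-detection scoring with unequal-variance
    d-prime, saccade-onset-locked presaccadic potential extraction with
    Mahalanobis trial matching, and the group-level statistical layer
    (repeated-measures ANOVA with least-square means and Holm-Sidak post
    hocs, MANOVA with Wilks' lambda gating, Kruskal-Wallis with Dunn's
    tests, and noncentral-F power computation). A synthetic-session
    generator with known ground truth makes every stage testable without
    patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nortest,
    emmeans,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
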