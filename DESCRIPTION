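Package: gazeshift
Title: Gaze-Shift Kinematics, Psychometrics and Spatial-Updating Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for eye-head gaze-shift experiments in
    virtual reality: seeded synthesis of head-yaw and gaze traces with
    main-sequence kinematics and vestibulo-ocular stabilization,
    velocity-threshold detection of head movements, amplitude-difference
    detection of saccades at low sample rates, fixation-duration metrics,
    maximum-likelihood cumulative-Gaussian psychometric fitting of
    two-alternative forced-choice localization data (point of horizontal
    alignment and just-noticeable difference), and within-subject
    repeated-measures inference with Greenhouse-Geisser correction,
    Bonferroni-corrected post hoc tests and per-subject gain-slope
    regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
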