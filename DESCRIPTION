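Package: tugseg
Title: Detection and Segmentation of Timed Up and Go Activities from
    Multi-IMU Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic detection and segmentation of the four activities of a
    Timed Up and Go (TUG) trial (standing up, walking, turning, sitting down)
    from multi-site inertial measurement unit recordings sampled at 60 Hz.
    Implements both the original healthy-adult detector set and the variant
    modified for people with Parkinson's disease (hip-angle gating from fused
    sacrum/thigh quaternions, shin-based gait detection with histogram
    adaptive thresholding, re-tuned band-pass cutoffs), transition
    localisation by extremum search around activity peaks, evaluation metrics
    (sensitivity/specificity, transition-time differences, ICC(2,1)), and a
    synthetic TUG kinematics generator with exact ground truth including
    Parkinsonian confounders.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
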