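Package: gaitmocap
Title: Magnetometer-Free Motion-Capture Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a full-body motion-capture gait analysis
    pipeline that works with magnetometer-free inertial measurement units
    (IMUs) or optical marker clusters (rigid bodies).  Provides anatomical
    ("Fitbody") calibration with heading correction for heading-less IMUs,
    forward-kinematic skeletal tracking, automatic gait-event detection from
    kinematic curves alone, spatio-temporal and kinematic gait variables,
    test-retest reproducibility statistics (ICC, SEM, MDC95), rigid-body
    marker-cluster geometry checks, and a parameterised walking-avatar
    simulator with ground-truth events for end-to-end validation without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
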