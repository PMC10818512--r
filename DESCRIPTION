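Package: strideval
Title: Stride-Level Validation of Foot-Worn Inertial Sensors Against
    Optical Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to estimate the foot strike angle and candidate
    forward-propulsion indicators from foot- and shank-mounted inertial
    measurement units during treadmill walking, to compute the same
    quantities from optical marker trajectories and force-plate recordings,
    and to run the stride-by-stride and within-subject agreement and
    correlation analyses (Bland-Altman limits of agreement, ICC(3,1),
    repeatability coefficient, Pearson correlation tables) that validate
    the sensor-based estimates against the optical gold standard. Includes
    a synthetic treadmill-gait generator producing mutually consistent
    marker, inertial, and ground-reaction-force streams with exact
    per-stride ground truth, so the whole pipeline is testable without any
    laboratory recording.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
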