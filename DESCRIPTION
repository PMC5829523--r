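Package: wheelfeat
Title: Feature Determination from Powered-Wheelchair Joystick Telemetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts driving features from 50 Hz powered-wheelchair joystick
    telemetry: tremor frequency (FFT and peak-count estimators), a weighted
    velocity-vector smoothness score, per-quadrant joystick position and
    velocity bias ellipses, obstacle-proximity bias against a dual-ellipse
    collision-damping field (DLAFF), and driving-time features. Includes the
    differential-drive kinematics, a linear remapping layer for adapting
    joystick throw, a small-sample classifier protocol for user and
    day-to-day-change identification, and a synthetic telemetry generator so
    the whole pipeline is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    class,
    nnet,
    zoo,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
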