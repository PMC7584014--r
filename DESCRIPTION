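Package: rungait
Title: Spatio-Temporal Running Parameters from Foot-Mounted Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for foot-mounted inertial measurement unit
    (IMU) recordings of endurance running. Provides functional sensor-to-shoe
    alignment from static and balance-board recordings via a singular value
    decomposition solution of the Wahba problem, gyroscope-based stride
    segmentation (initial contact, midstance, toe off), zero-velocity-update
    strapdown integration of the per-stride foot trajectory with quaternion
    orientation estimation and linear velocity dedrifting, and computation of
    six spatio-temporal parameters: stride time, ground contact time, stride
    length, average stride velocity, sole angle, and frontal-plane range of
    motion. Includes evaluation tools (phase-wise Pearson correlations between
    sensor positions, signed parameter errors, zero-velocity-violation error,
    median/IQR aggregation by speed bin) and a rigid-body IMU simulator that
    generates multi-position foot sensor data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
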