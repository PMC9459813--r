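Package: stairclimbr
Title: Stair Climb Power Estimation from a Lumbar-Worn Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects stair-climbing foot contacts from the vertical
    acceleration of a lumbar-worn inertial measurement unit and estimates
    stair climb power (SCP), the clinical measure of lower-limb muscular
    function assessed with the four-step Stair Climb Power Test. Provides
    the full processing chain: reading and resampling six-axis IMU
    recordings, slicing by activity annotations, sliding-window feature
    extraction (148 accelerometer and gyroscope features), wavelet-based
    initial-contact detection with a misdetection filter, the stopwatch
    and sensor-based SCP formulas, a grouped cross-validation protocol
    for stair-walking and ascent/descent classifiers, and
    method-agreement statistics (Pearson, ICC(2,1), Bland-Altman, Welch
    t-tests). A synthetic lumbar-IMU trial simulator with known ground
    truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    randomForest,
    class,
    glmnet,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
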