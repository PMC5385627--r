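Package: turndetect
Title: Turning Detection and Analysis from a Lower-Back Inertial Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects and characterises turns (magnitude, duration, direction)
    from a six-degrees-of-freedom inertial measurement unit worn on the lower
    back. Orientation is initialised from a quasi-static accelerometer window
    and propagated sample-by-sample with a Rodrigues rotation-matrix update of
    the gyroscope signal; turns are segmented from the unwrapped yaw trace at
    direction reversals, brief intra-turn hesitations are merged, and events
    are filtered by magnitude and duration thresholds. Includes event-level
    validation against reference annotations (confusion counts, sensitivity,
    specificity, accuracy, predictive values, Cohen's kappa, Bland-Altman
    agreement of detection times, and magnitude-threshold sweeps) and a seeded
    synthetic-recording generator for end-to-end testing without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
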