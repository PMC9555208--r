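Package: mothmpc
Title: Inertial Dynamics and Receding-Horizon Control of Hawkmoth Flower Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates a hawkmoth (Manduca sexta) as two coupled rigid
    ellipsoids (head-thorax and abdomen joined by a damped torsional spring)
    tracking a vertically oscillating flower with a Monte-Carlo receding-horizon
    controller, under fully actuated and underactuated treatments. Provides the
    flight-performance metrics (non-dimensional tracking error, mechanical work,
    cost of transport) and their treatment-level statistics, path statistics for
    free-flight head tracks (RMS kinematics, sliding-window tortuosity,
    box-counting dimension, segment spectra, incidence tests), and an FFT-based
    estimator of the thoracic-abdominal torsional spring constant from
    forced-oscillation trials, together with synthetic-data generators for all
    input kinds.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
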