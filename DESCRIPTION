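Package: cupball
Title: Quantitative Assessment of Cup-and-Ball Object Transport Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the cup-and-ball object
    transport task used in quantitative upper-extremity assessment. Models the
    cup and rolling ball as a kinematically driven cart-and-pendulum system,
    preprocesses overhead-camera trial recordings (zero-phase Butterworth
    filtering, movement-axis projection, velocity-threshold segmentation), and
    computes four per-trial performance metrics: movement time, spectral arc
    length (SPARC) smoothness, an energy-margin risk of losing the ball, and
    mutual information between cup and ball phases. Within- versus
    between-subject consistency is quantified by intraclass correlation
    coefficients from random-intercept models. Includes a deterministic
    synthetic-trial generator emulating the device's 80 Hz camera output for
    testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
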