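Package: ipcfit
Title: Intermittent Postural Control Models for Quiet-Standing Sway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and direct maximum-likelihood estimation of the
    intermittent postural control (IPC) model of quiet-standing sway: a
    stochastic delay differential equation for the inverted-pendulum tilt
    angle in which delayed corrective torque switches on only in a region of
    the phase plane. Provides an Euler-Maruyama simulator with a delay
    buffer, a continuous-discrete Kalman filter with lag interpolation,
    backward extrapolation of initial conditions and two-step prediction
    across switching thresholds, bounded differential-evolution likelihood
    optimization, AIC comparison of nested model variants, and
    parameter-recovery simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
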