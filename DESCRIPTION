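Package: dosepulse
Title: Dynamic Hysteresis and Dose-Effect Scaling for Periodically Treated
    Tumor-Immune Dynamics
Version: 1.0.0
Authors@R:
    person("dosepulse", "developers", email = "dosepulse@example.org",
           role = c("aut", "cre"))
Description: Simulates a logistic tumor growth model with a saturating
    immunosurveillance term under periodic external intervention (pulsed
    radio- or chemotherapy schedules), integrates the forced ODE to its
    steady periodic cycle with an adaptive Dormand-Prince solver, measures
    the dynamic hysteresis loop traced by tumor density against the
    intervention waveform (loop area, dose cumulant, cycle statistics,
    optimal dose and effective duty-cycle features), and collapses the
    amplitude-by-duty-cycle dose-effectiveness surface onto a universal
    quadratic law by per-amplitude rescaling and least-squares fitting.
    Includes a synthetic-fixture generator with closed-form ground truth so
    every analysis stage is testable without integrating the ODE, tidy CSV/
    JSON serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
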