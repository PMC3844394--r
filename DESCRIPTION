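Package: p53loop
Title: Disturbance-Rejection Analysis of the p53-Mdm2 Negative Feedback Loop
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Control-theoretic and stochastic analysis of the p53-Mdm2
    negative feedback loop. Provides closed-form disturbance-rejection
    metrics (steady-state error, damping ratio, percent overshoot) for a
    linear continuous model of the loop, a discrete-time model with
    z-plane pole and Monte-Carlo robustness analysis of transcriptional
    versus post-translational suppression, normalized least-mean-squares
    (NLMS) adaptive tracking of time-varying feedback weights from
    two-channel p53/Mdm2 time series, a nonlinear mechanistic model with
    Hill activation, Michaelis-Menten degradation and transcription-to-
    translation delay under a step-disturbance protocol, exact Gillespie
    stochastic simulation of the corresponding reaction network, and a
    synthetic-data generator emulating single-cell fluorescence time
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
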