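Package: bioshadow
Title: Digital Shadow of Cell Expansion in a Glucose-Controlled Perfusion Bioreactor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic simulator and real-time soft sensor of T cell
    expansion in a perfusion bioreactor whose perfusion rate is adjusted by a
    PI(D) controller holding the glucose concentration at a set-point. The
    cell growth law is a two-parameter special case of the Richards
    generalized-logistic model with a lag period; glucose, lactate and
    (optionally) dissolved-oxygen balances are integrated by a clamped
    forward-Euler scheme at sensor cadence. Includes a synthetic online-data
    generator (sensor noise, bubble artifacts, order-2 Butterworth lowpass),
    Levenberg-Marquardt parameter estimation in full-run (endpoint-
    constrained) and real-time (truncated-window) regimes, and pseudo-real-
    time replay producing cell-concentration nowcasts, forecasts, minimum
    confidence bands and harvest-time predictions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    minpack.lm,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
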