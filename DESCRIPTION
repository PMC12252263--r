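Package: preaction
Title: Detecting Preliminary Actions in Karate Punches from Wrist-Worn
    Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-stage analysis of 6-axis wrist inertial recordings of
    karate sparring (kumite). A sliding-window autocorrelation stage
    (GWA) detects quasi-periodic footwork, refines segment boundaries by
    gradually shrinking windows, fuses per-axis decisions, and smooths
    footwork segments with a moving average. A detection stage (GLID)
    cuts the punch at its striking timing, reverses it, and tracks the
    dynamic time warping distance to a reference set of pre-action-free
    punches as the analysis window grows; the gap between the first
    local minimum and the following local maximum of that distance
    profile decides whether a preliminary action ("pre-action") preceded
    the punch. Includes a seeded synthetic-data generator with exact
    ground truth, an end-to-end pipeline, and evaluation metrics.
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
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
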