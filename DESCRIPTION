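Package: stopgo
Title: Stop-and-Go T Cell Motility and Ratiometric Calcium Imaging Analysis
Version: 0.1.0
Authors@R:
    person("stopgo", "developers", email = "stopgo@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of calcium-regulated
    stop-and-go T cell motility. Provides track-derived motility statistics
    (instantaneous velocity, arrest coefficient, pause durations, turn
    angles, directionality ratio, mean-squared displacement and motility
    coefficient), ratiometric analysis of tandem green/red genetically
    encoded calcium indicators (photobleach correction, ratio
    normalization, elevated/basal classification), detection of calcium
    transients in two-channel XY-T image stacks (autofluorescence masking,
    spatiotemporal connected components, ellipsoid metrics, sparkle versus
    cell-wide classification), calcium-rise-triggered velocity averaging,
    and nonparametric group comparison (Mann-Whitney U, Hodges-Lehmann).
    A synthetic-data module generates persistent-random-walk tracks with
    pause-coupled calcium transients and rasterized image stacks with
    known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
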