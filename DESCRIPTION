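Package: fociscreen
Title: High-Content Time-Lapse Analysis of Transient Nuclear Foci and
    RNAi Screen Scoring
Version: 0.1.0
Authors@R:
    person("fociscreen", "maintainers", email = "maintainers@fociscreen.dev",
           role = c("aut", "cre"))
Description: Detects and counts transient nuclear protein bodies in
    single-channel fluorescence time-lapse microscopy, tracks nuclei across
    frames by the overlap method, aggregates per-track focus-count time
    series into a mean-bodies-per-cell readout, and scores siRNA screens by
    replicate-wise log2 Z-scores against negative-control positions.
    Includes illumination correction, masked-median background subtraction,
    power log-log slope blur QC, dead/mitotic-cell filtering, a synthetic
    time-lapse generator with per-cell ground truth, Manders and
    object-based colocalization, proximity-ligation radius scoring, line
    profiles, and exponential FRAP recovery fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
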