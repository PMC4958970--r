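Package: ballsift
Title: Rolling-Ball Sifting for Carotid Bruit Auscultation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computer-aided auscultation of carotid sounds.  Separates
    low-frequency transmitted heart sounds from intermittent high-frequency
    systolic bruits with a rolling-ball sifting algorithm: an alpha-shape
    tangibility criterion selects the data points touchable by balls rolled
    above and below the waveform, monotone cubic interpolation of the sifted
    extrema defines upper/lower envelopes and a local zero, and the riding
    high-frequency component is extracted inside merged candidate segments.
    Includes classical empirical-mode-decomposition sifting of the first
    intrinsic mode function, autocorrelation heart-rate estimation, a
    zero-phase FIR high-pass comparison detector, case-level decision rules
    with a five-row inspection figure, a synthetic carotid-sound generator
    with ground truth, and exact binomial diagnostics (Clopper-Pearson
    intervals, Cohen's kappa) for 2x2 count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
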