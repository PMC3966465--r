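Package: amfmtex
Title: Despeckle Filtering and Multiscale AM-FM Texture Analysis of Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for speckle reduction and multiscale Amplitude-Modulation
    Frequency-Modulation (AM-FM) texture analysis of B-mode ultrasound images,
    with an emphasis on the carotid intima-media complex. Implements eight
    classical despeckle filters (local-statistics, Wiener, Kuwahara,
    minimum-speckle-index, median, hybrid median, speckle-reducing anisotropic
    diffusion, and coherence-enhancing nonlinear diffusion), an FFT-based
    analytic-image demodulator with dyadic low/medium/high frequency scales,
    instantaneous amplitude and frequency texture features with rank-based
    group comparison, a fully specified synthetic carotid phantom with
    multiplicative speckle, and an evaluation harness that measures
    instantaneous-frequency estimation error region by region.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    png,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
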