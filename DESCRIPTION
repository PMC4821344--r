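Package: fcsfit
Title: In Vivo Fluorescence Correlation Spectroscopy and FRAP Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of fluorescence correlation spectroscopy (FCS) and
    fluorescence recovery after photobleaching (FRAP) measurements of
    fluorescently tagged DNA-binding proteins in living cells.
    Provides photobleach detection and excision on binned photon-count
    traces, a multi-tau autocorrelator with per-segment averaging and
    dispersion estimates, weighted least-squares fitting of
    multi-component 3D-Gaussian free/anomalous diffusion models with
    multi-start optimization, model-count adjudication by corrected AIC,
    nested F-tests and a parameter-dispersion screen, conversion of
    diffusion times to diffusion coefficients and apparent molecular
    masses, single-exponential FRAP recovery fitting, and a Brownian
    dynamics Monte-Carlo simulator of fluorescence fluctuation traces
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
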