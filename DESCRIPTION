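Package: dlsann
Title: Neural-Network-Assisted Dynamic Light Scattering Particle Sizing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sizing suspended particles and living cells from
    dynamic light scattering (DLS) intensity time-series. Simulates
    realistic DLS signals by spectral synthesis from the Lorentzian
    power spectrum of Brownian intensity fluctuations (with power-grid
    and broadband noise models), computes and normalizes intensity
    autocorrelations, estimates hydrodynamic diameters by the classical
    single-exponential least-squares fit, and trains a 350-26-1
    feed-forward neural network with Levenberg-Marquardt so that sizing
    reduces to a single matrix evaluation. Includes an end-to-end
    pipeline for long-duration monitoring experiments such as yeast
    fermentation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
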