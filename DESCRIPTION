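Package: hsdmie
Title: Hyper-Spherical Diffusion Models by the Integral-Equation Method
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: First-passage-time distributions and joint response-time/choice
    likelihoods for hyper-spherical diffusion models (HSDM) of
    continuous-response decisions, with constant or linearly collapsing
    decision thresholds. The first-passage density of the underlying
    squared-Bessel (Feller) process through a time-dependent squared boundary
    is computed from a second-kind Volterra integral equation discretized by
    the rectangle left-point scheme; the classical Bessel-series solution is
    provided for constant thresholds as an independent cross-check. Includes
    an Euler-Maruyama trial simulator, maximum-likelihood estimation by
    differential evolution, parameter-recovery studies, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
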