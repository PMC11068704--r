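Package: wavenetid
Title: Wavelet-Network Identification of Single-Neuron Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven identification of single-neuron dynamics with
    wavelet networks (wavenets). Simulates four conductance-based and
    FitzHugh-Nagumo-type neuron models under designed applied currents,
    builds multiresolution spline wavelet frames (tensor products of
    displaced scaling functions and wavelets plus identity terms), fits
    the linear-in-parameters network by ridge-regularized least squares
    via chunked normal equations, and evaluates one-step-ahead and
    free-running predictions with regression, cosine-similarity,
    cross-correlation and interspike-interval indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
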