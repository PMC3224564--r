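Package: ecbs
Title: Extreme-Value Model-Based Circular Binary Segmentation for Array CGH Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Segmentation of array comparative genomic hybridization (aCGH)
    log2-ratio profiles into regions of constant DNA copy number by circular
    binary segmentation (CBS). Instead of evaluating the significance of each
    candidate change-point by permutation, the significance of the circular
    maximal-t statistic is read from a precomputed lookup model: null
    log2-ratio series are simulated from the Pearson distribution system over
    a grid of probe counts, skewness and kurtosis, the resulting maximal-t
    null distributions are fitted by the generalized extreme value (GEV)
    distribution, and segmentation queries the fitted parameter tables by
    trilinear interpolation. A permutation test with early stopping is kept
    as the fallback for short segments and as an internal validation oracle.
    Includes the simulation designs used to validate calibration and power.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
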