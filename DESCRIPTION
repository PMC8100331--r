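Package: crba
Title: Competitive Rate-Based Approximation of Spiking Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised competitive learning with a rate-based, one-pass
    approximation of competitive spiking neural networks (CSNN). Implements the
    five-step competitive rate-based algorithm (CRBA): dot-product ranking of
    neurons by predicted firing rate, winner selection, predicted spike counts,
    discrete expectation-maximization weight updates, and homeostatic adaptive
    firing thresholds. Ships a time-stepped leaky integrate-and-fire reference
    simulator with Poisson rate coding, spike-timing-dependent plasticity,
    lateral inhibition and adaptive thresholds, together with the closed-form
    membrane-potential and first-spike-time solutions used to validate the
    approximation. Includes neuron labeling and maximum-voting inference,
    parameter transfer from the rate-based model to the spiking network, a
    synthetic clustered-data generator, IDX/CSV readers and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
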