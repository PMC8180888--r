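Package: snntraj
Title: Event-Based Trajectory Prediction with Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Emulates a frame-difference/difference-of-Gaussians event camera,
    trains a multi-layer convolutional spiking neural network of leaky
    integrate-and-fire neurons with axonal delay selection, lateral inhibition,
    adaptive homeostatic thresholds and a simplified spike-timing-dependent
    plasticity rule, and decodes the output spikes with per-filter quadratic
    regressions to predict the reception point of ballistic ball trajectories.
    Includes a synthetic ballistic-scene generator with exact ground truth,
    direction- and speed-selectivity analyses against occurrence-normalised
    tuning curves, and unsupervised motion-tracking diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
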