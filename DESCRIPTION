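Package: elscape
Title: Energy-Landscape Analysis of Binarized Network Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits pairwise maximum-entropy (Ising) models to binarized
    multichannel time series, constructs the resulting energy landscape
    (local minima, attractor basins, disconnectivity tree), simulates
    Metropolis-Hastings random walks on it, and summarizes the dynamics as
    per-attractor dwelling times and pairwise transition frequencies whose
    Gini coefficients serve as polarization indices. Includes preprocessing
    routes for network-averaged fMRI-like recordings and high-dimensional
    hidden-state trajectories (window selection, k-means node clustering,
    cluster-mean binarization), a synthetic-data generator with known
    ground truth, and group-comparison and brain-behavior correlation
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
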