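Package: patsep
Title: Information-Geometric Pattern Separation for Two-Neuron Spike Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates pattern separation in a controlled two-neuron system
    whose joint spiking law forms a three-dimensional statistical manifold
    with mutually orthogonal coordinates: the marginal firing probabilities
    of each neuron and a log-odds-ratio correlation. Provides the Fisher
    information metric on that manifold, seeded sampling of binary firing
    patterns and their spike-time representations, eight spike-train
    similarity indices (Pearson correlation, cosine similarity, scaling
    factor, bin-wise Hamming distance, SPIKE similarity, nearest-neighbour
    estimated mutual information over Wasserstein spike distances, transfer
    entropy, and relative redundancy reduction), and sweep experiments that
    measure how each index responds to controlled changes in correlation or
    firing rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
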