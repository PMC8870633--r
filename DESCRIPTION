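Package: snnclust
Title: Cluster-Grouped Spiking Neural Networks with Structural and
    Synaptic Co-Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds, trains and evaluates cluster-grouped spiking neural
    networks for small-sample image classification. Images are converted
    to spike trains by oriented convolution, max pooling and
    latency (rank-order) coding; each homogeneous cluster of
    leaky-integrate-and-fire neurons is trained on a bootstrap subset with
    a bipolar (encouraging/punishing teacher signal) supervised STDP rule;
    structural learning prunes synapses whose weights barely changed
    during training; a deterministic spike-count accumulator aggregates
    the cluster votes. Includes a synthetic stroke-digit generator, an
    MNIST IDX reader, and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
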