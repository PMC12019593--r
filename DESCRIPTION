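Package: hetquant
Title: Heterogeneous Spike-Phase Quantization for Chemosensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an olfactory-bulb-inspired signal-conditioning network
    for electronic-nose sensor arrays: analog divisive (l1) normalization in a
    glomerular layer, transduction of normalized activations into gamma-cycle
    spike-phase codes by columns of leaky integrate-and-fire mitral cells with
    heterogeneous (1/x-distributed) synaptic gains, and a granule-cell feature
    layer trained by spike-timing-dependent plasticity. Includes generators
    for synthetic concentration- and saturation-limited chemosensor datasets
    built on a sparsity-tuned hierarchical affinity matrix, exact Jenks
    natural-breaks calibration of data-aware quantization schemes, and an
    evaluation harness measuring spiking-layer utilization regularization and
    information retention via nested cross-validated RBF support vector
    machines.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
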