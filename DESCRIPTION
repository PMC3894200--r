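Package: arborsim
Title: Stochastic Neurite Outgrowth, Geometry-Based Synapse Formation and
    Network Connectivity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grows three-dimensional networks of morphologically realistic
    cortical layer 2/3 pyramidal neurons with a stochastic (Van Pelt-type)
    neurite outgrowth model, places candidate synapses wherever crossing
    axonal and dendritic line pieces come within a threshold orthogonal
    distance of each other (Peters' rule), and quantifies the emergent
    synapse distributions and neuron-level connectivity, including
    small-world graph topology. Includes morphometric analysis of simulated
    or SWC-imported arbors, a genetic-algorithm fitter for the outgrowth
    parameters, and a reproducible end-to-end pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
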