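Package: stanflow
Title: Spatial-Temporal Attention Normalizing Flows for Neural Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generative modeling of neuronal interspike intervals with a
    spatial-temporal attention encoder over population spiking history and a
    conditional normalizing flow (STAN-flow). Includes a population spike-train
    simulator with planted synchronization structure, classical synchronization
    indices (shift-predictor-corrected cross-correlogram ESI and kernelized
    binless similarity), stimulus-clustering evaluation of attention summary
    matrices, unit-ablation analysis, Poisson-Surprise burst detection with a
    projection-neuron/local-interneuron classifier, z-scored peristimulus time
    histograms, response indices, and dissimilarity indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    glmnet,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
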