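Package: synconn
Title: Synaptic Density Similarity Connectomes and Causal Covariance
    Networks from PET
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds individual synaptic density similarity connectomes from
    SV2A PET standardized-uptake-value (SUV) volumes by kernel density
    estimation of regional intensity distributions and symmetric
    Kullback-Leibler similarity (KLSE), performs edgewise and regional
    case-control inference with false discovery rate control, and maps
    directed degeneration structure with causal synaptic covariance
    networks: signed-path-coefficient Granger causality applied to
    cross-sectional volumes sequenced by clinical disease stage. Includes a
    synthetic cohort generator with a planted seed-to-striatum-to-neocortex
    propagation ordering so that every analysis stage can be validated
    against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, StatisticalMethod, Software
RoxygenNote: 7.3.3
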