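Package: SpatialTucker
Title: Graph-Regularized Nonnegative Tucker Decomposition for Spatial
    Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Masked, graph-regularized nonnegative Tucker decomposition of
    three-way (y, x, gene) spatial gene-expression tensors. Spot-level count
    matrices on a Visium-style grid are arranged into a tensor, factorized by
    multiplicative updates under a Cartesian-product graph-Laplacian penalty
    built from two spatial chain graphs and a gene interaction network, and
    the fitted model is used to impute missing expression and to construct
    per-gene-component spatial activity maps. Includes spot-wise
    cross-validation, imputation and region-concordance metrics, k-means
    spatial-domain detection, and a synthetic-data generator emulating the
    statistical structure the model assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
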