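Package: scdenoise
Title: Self-Supervised Denoising of Single-Cell Expression Data with
    Weighted k-Nearest-Neighbor Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Denoises cells-by-genes expression matrices by weighted
    k-nearest-neighbor averaging and graph diffusion, with every
    hyperparameter (number of principal components, number of neighbors,
    edge-weight mode, diffusion depth) selected by a self-supervised
    leave-self-out mean-squared-error objective: each cell's expression is
    predicted from its neighbors only, via a zero-diagonal right-stochastic
    transition matrix, so the objective can be minimized without ground
    truth. Includes count preprocessing (cell/gene filtering, median depth
    normalization, Freeman-Tukey variance stabilization), molecular
    cross-validation for PCA rank selection on raw counts, singular-value
    variance-structure diagnostics for detecting oversmoothing, synthetic
    count-data generators with known ground truth, and readers/writers for
    Matrix Market, delimited text and HDF5 matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    tools,
    utils,
    data.table,
    RANN
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    rhdf5,
    withr
Config/testthat/edition: 3
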