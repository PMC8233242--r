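Package: masslasso
Title: Fast L1-Regularized Linear Models for Mass-Univariate Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates L1-regularized (lasso) linear models for many
    response series sharing a single design matrix, the mass-univariate
    setting typical of voxel-wise fMRI analysis. Provides a coordinate
    descent solver with a precomputed Gram matrix, covariance updates,
    active sets and warm-started regularization paths, and a batched
    ADMM solver with cached factorizations and a Woodbury branch for
    overparameterized designs. Includes sparse coefficient storage,
    readers for delimited matrix files and NIfTI volumes with masks,
    synthetic benchmark generators and an independent proximal-gradient
    reference solver for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    data.table,
    parallel,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
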