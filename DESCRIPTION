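Package: acmtf
Title: Structure-Revealing Coupled Matrix and Tensor Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint factorization of a higher-order tensor and one or more
    matrices that share a mode, for multi-block data fusion in metabolomics
    and related fields. Implements the structure-revealing coupled matrix and
    tensor factorization (ACMTF) model: a CANDECOMP/PARAFAC decomposition with
    unit-norm factor columns and explicit per-dataset component weights that
    are sparsified with a smoothed l1 penalty, so that components shared
    across datasets and components confined to a single dataset are exposed
    automatically. Also provides the unweighted coupled factorization (CMTF)
    baseline, support for incomplete data via observation masks, an
    all-at-once nonlinear conjugate gradient fitter with a multi-start
    protocol, synthetic coupled-data generators, and recovery diagnostics
    (permutation-matched factor match scores, weight extraction and
    shared/unshared classification).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
Config/testthat/edition: 3
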