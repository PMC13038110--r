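Package: duodecon
Title: Dual-Branch Deconvolution of Bulk RNA-seq into Cell-Type Proportions
    and Cell-Type-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deconvolves bulk RNA-seq samples into cell-type proportions and
    per-sample cell-type-specific gene expression profiles with a dual-branch
    neural network: a shared linear feature extractor feeding a multilayer
    perceptron head for proportions and a one-dimensional U-Net head for
    expression profiles, trained jointly on pseudobulk samples simulated from
    an annotated single-cell reference with Dirichlet-distributed cell-type
    proportions.  Includes a synthetic-reference generator with planted marker
    structure, one-vs-rest Wilcoxon marker selection, concordance and error
    metrics, and a combinatorial cell-state patient-subtyping framework with
    log-rank screening, intersection-over-union merging, consensus assignment
    and external-cohort transfer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
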