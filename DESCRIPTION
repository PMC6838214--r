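Package: repsum
Title: Summary Statistics, Divergences, and Model Validation for Immune
    Receptor Repertoires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes biologically interpretable summary distributions over
    annotated adaptive immune receptor (BCR/TCR) repertoires in the AIRR
    Community Rearrangement format, and compares repertoires through
    per-summary statistical divergences (Jensen-Shannon divergence for scalar
    distributions, l1 divergence for categorical counts).  Includes
    convergence-controlled subsampling approximations for expensive
    distributions, an unbiased batched estimator for nearest-neighbor
    distance distributions, a lasso-path procedure that ranks sequence-level
    summaries by how well they discriminate datasets, log relative average
    divergence (LRAD) scores for validating generative repertoire
    simulators, classical multidimensional scaling of divergence matrices,
    and a fully parameterized synthetic-repertoire generator for testing
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
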