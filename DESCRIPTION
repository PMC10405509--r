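Package: willham
Title: Maternal Animal Models with Direct-Maternal Genetic and
    Environmental Covariances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based genetic evaluation for maternally influenced
    traits such as juvenile body weight in broilers.  Implements the
    Willham maternal animal model family with a direct-maternal genetic
    covariance and, via a fixed dummy-residual reparameterization that
    turns the residual into an estimable random effect, a direct-maternal
    environmental covariance between the residual on a dam's own record
    and her permanent environmental effect on offspring.  Provides sparse
    Henderson mixed-model equations built on the inverse numerator
    relationship matrix, restricted maximum likelihood (average
    information with finite-difference scores and EM steppers),
    likelihood-ratio tests, a stochastic breeding-program simulator with
    overlapping selection rounds and truncation selection on BLUP
    breeding values, and cross-validation statistics (forward and
    paternal half-sib prediction, Legarra-Reverter correlation, and
    inflation slopes with genetic-trend correction).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
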