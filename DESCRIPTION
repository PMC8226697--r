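Package: rrtdm
Title: Random Regression Test-Day Models for Somatic Cell Score and
    Production Traits via Gibbs Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayesian estimation of genetic parameters for dairy test-day
    records with a multiple-trait random regression animal model. Legendre
    polynomial covariance functions describe additive genetic and permanent
    environmental (co)variances across days in milk; (co)variance components
    are estimated by Gibbs sampling with inverted-Wishart full conditionals
    over a pedigree relationship structure. Includes test-day record editing
    and somatic cell score transformation, pedigree inbreeding and sparse
    relationship-matrix inverses, a synthetic-herd simulator with known truth
    for parameter-recovery studies, and post-processing into daily
    heritabilities and between-trait genetic, permanent environmental, and
    phenotypic correlation surfaces.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
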