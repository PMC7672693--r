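Package: dynherit
Title: Dynamic SNP-Heritability from Longitudinal Phenotypes with
    Gaussian Process Priors
Version: 0.1.0
Authors@R:
    person("Elias", "Koski", email = "elias.koski@example.org",
           role = c("aut", "cre"))
Description: Bayesian estimation of time-varying genetic and environmental
    variance components, and of dynamic SNP-heritability h2(t), from
    longitudinal phenotypes and a genomic relationship matrix. Log-variance
    curves receive Matern (nu = 3/2) Gaussian-process priors; posterior
    inference uses a whitened parameterization sampled with elliptical slice
    sampling for the curves and adaptive random-walk Metropolis for the
    length scales, with the likelihood factorized through a single
    eigendecomposition of the relationship matrix. Includes a two-stage
    baseline (independent per-time-point fits followed by GP smoothing),
    VanRaden's genomic relationship matrix with mean imputation of missing
    markers, posterior breeding values with SNP-effect back-transformation,
    synthetic-data generators for longitudinal polygenic and twin designs,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
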