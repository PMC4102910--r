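Package: mlsemm
Title: Non-Linear Multilevel Structural Equation Mixture Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Specification, simulation, and Bayesian estimation of two-level
    structural equation models with finite mixtures on both levels and
    non-linear (polynomial, interaction, and truncated-power spline) effects
    among latent variables and covariates. Models are declared through a
    small term language, simulated from their generative process, and fitted
    by a Metropolis-within-Gibbs sampler with conjugate updates for
    coefficients and precisions, data augmentation for latent classes,
    latent variables, ordinal indicators, and missing-at-random cells, and
    ordered-increment priors that prevent mixture label switching.
    Convergence (estimated potential scale reduction), posterior summaries,
    and deviance information criterion comparisons are included, together
    with a Gauss-Hermite quadrature evaluator of the marginal likelihood for
    small models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
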