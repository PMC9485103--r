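Package: giirr
Title: Geometry-Informed Irreversible Perturbations for Langevin Samplers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A toolkit for unadjusted Langevin sampling with reversible and
    irreversible perturbations, including the geometry-informed irreversible
    perturbation (GiIrr) of Riemannian-manifold Langevin dynamics. Provides
    five Euler-Maruyama samplers sharing one invariant density, stochastic
    (minibatch) gradient support, estimator-quality diagnostics (ensemble
    bias/variance/MSE, batch-means asymptotic variance, kernelized Stein
    discrepancy with the inverse multiquadric kernel), an exact discrete-time
    linear-Gaussian stationary-law oracle, and seeded experiment presets for
    four example posteriors: a linear-Gaussian model, the mean and standard
    deviation of a normal distribution, Bayesian logistic regression, and
    Bayesian independent component analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    parallel,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
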