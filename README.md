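# giirr

Langevin samplers with reversible and irreversible perturbations for
Bayesian computation, centred on the **geometry-informed irreversible
perturbation (GiIrr)** of Riemannian-manifold Langevin dynamics — for
statisticians and computational scientists who estimate posterior
expectations with unadjusted (stochastic-gradient) Langevin algorithms and
want lower asymptotic variance for the same number of gradient
evaluations.

## The idea

The Langevin diffusion
dθ = β ∇log π(θ) dt + √(2β) dW has invariant density π, so long-run
averages of a discretized trajectory estimate posterior expectations. Two
classical modifications keep π invariant: a Riemannian-metric (reversible)
perturbation **B**(θ), giving drift β[**B**∇log π + ∇·**B**] and noise
√(2β**B**); and an irreversible drift **J**∇log π for a constant
skew-symmetric **J**. GiIrr couples them through the state-dependent skew
matrix

    C(θ) = (J B(θ) + B(θ) J) / 2

with drift (β**B** + **C**)∇log π + ∇·(β**B** + **C**) and noise √(2β**B**),
which still leaves π invariant and — when **B** genuinely helps —
outperforms irreversibility that ignores the geometry. The package
provides all five samplers (`LD`, `RM`, `Irr`, `RMIrr`, `GiIrr`) behind
one interface, minibatch (stochastic-gradient) drift estimates, and the
full diagnostic kit: batch-means asymptotic variance, ensemble
bias/variance/MSE, kernelized Stein discrepancy (inverse multiquadric
kernel), and an exact discrete-time stationary-law oracle for
linear-Gaussian targets.

Four worked posteriors ship with seeded synthetic-data generators: a
linear-Gaussian model, the (μ, σ) parameters of a normal sample, Bayesian
logistic regression, and Bayesian ICA (blind source separation).

## Worked example

Compare all five samplers on the normal-parameters posterior (N = 30 data
from N(0, 10²), Fisher metric B = (σ²/N)·diag(1, ½), J = 2[[0,1],[−1,0]],
h = 10⁻³, K = 10⁶ steps, minibatch n = 6, burn-in time 10):

```r
library(giirr)
report <- run_experiment(
  experiment_preset("normal_params", n_chains = 10),
  kinds = c("LD", "RM", "Irr", "RMIrr", "GiIrr"),
  base_seed = 1)
tidy(report)
#> # A tibble: 10 × 6
#>    kind  observable avar_mean avar_std n_chains n_failed
#>    <chr> <chr>          <dbl>    <dbl>    <int>    <int>
#>  1 LD    phi1           68.5    43.0         10        0
#>  2 LD    phi2        13888.   8574.          10        0
#>  3 RM    phi1           21.1     8.70        10        0
#>  4 RM    phi2         5391.   2015.          10        0
#>  5 Irr   phi1            8.63    2.51        10        0
#>  6 Irr   phi2         2487.   1038.          10        0
#>  7 RMIrr phi1            9.29    1.70        10        0
#>  8 RMIrr phi2         1946.    621.          10        0
#>  9 GiIrr phi1            1.96    0.399       10        0
#> 10 GiIrr phi2          594.    231.          10        0
glance(report)$best_kind
#> [1] "GiIrr"
```

`avar_mean` is the mean (over chains) batch-means estimate of the
asymptotic variance of the long-run average of φ₁ = μ + σ and
φ₂ = μ² + σ²: time × variance of the estimator, so smaller means a more
efficient sampler at equal budget. Irreversibility alone (`Irr`) cuts the
LD asymptotic variance by ~8×; informing it with the Fisher geometry
(`GiIrr`) buys another ~4× and wins on both observables. `avar_std` is the
across-chain spread of the per-chain estimates (each of the 10 chains is
noisy; the mean is what the study reports).

The discrete-time oracle quantifies discretization bias exactly for
constant-coefficient chains — e.g. a 1-D chain with drift −θ/2 and unit
noise covariance at h = 0.01:

```r
em_stationary_law(matrix(0.5), h = 0.01)$covariance
#>          [,1]
#> [1,] 1.002506   # continuous-time limit: 1
```

`autoplot(report)`, `autoplot(ksd(...))`, `tidy()` and `glance()` methods
give ggplot2 figures and tibble summaries throughout. A thin CLI wraps the
same functions:

```sh
Rscript inst/cli/giirr run --preset normal_params --kinds ld,giirr \
    --chains 10 --seed 1 --out out/
Rscript inst/cli/giirr ksd --preset gaussian --kinds ld --chains 5 --max-k 10000
Rscript inst/cli/giirr oracle --kind giirr
```

See the methods vignette
(`vignettes/geometry-informed-irreversible-langevin.Rmd`) for the model,
the numerical choices, the synthetic-data laws, and known limitations of
the desk-scale study conditions.

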