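test_that("skew generators produce the documented patterns", {
  # canonical all-ones upper triangle scaled by delta
  expect_equal(build_skew("dense_upper_ones", 3, delta = 2),
               2 * rbind(c(0, 1, 1), c(-1, 0, 1), c(-1, -1, 0)))

  # every pattern is exactly skew-symmetric
  for (J in list(build_skew("dense_upper_ones", 4, delta = 0.3),
                 build_skew("random_pm1", 20, seed = 9, norm_target = 1),
                 build_skew("kronecker", 9, norm_target = 2))) {
    expect_identical(J + t(J), matrix(0, nrow(J), nrow(J)))
  }

  # random_pm1: requested spectral norm, reproducible, +/-1 pattern
  J <- build_skew("random_pm1", 20, seed = 9, norm_target = 1)
  expect_lt(abs(max(svd(J)$d) - 1), 1e-12)
  expect_identical(J, build_skew("random_pm1", 20, seed = 9, norm_target = 1))
  expect_true(all(abs(J[lower.tri(J)] / max(abs(J))) %in% c(1)))

  # kronecker: (I (x) C0) + (C0 (x) I) rescaled
  C0 <- build_skew("dense_upper_ones", 3)
  raw <- kronecker(diag(3), C0) + kronecker(C0, diag(3))
  expect_equal(build_skew("kronecker", 9, norm_target = 1),
               raw / norm(raw, "2"))
  expect_error(build_skew("random_pm1", 5, norm_target = -1), "norm_target")
  expect_error(build_skew("kronecker", 8), "perfect square")
})

test_that("geometry-informed skew matrix and its divergence match closed forms", {
  # B = I reverts to the constant skew
  J <- build_skew("dense_upper_ones", 3, delta = 1.5)
  expect_equal(giirr_C(diag(3), J), J)

  # Fisher metric of the normal-parameters target: C = (3 sigma^2 / 4N) J
  fx <- np_fixture()
  B <- fx$target$metric(c(0, 10))          # sigma = 10, N = 30
  expect_equal(giirr_C(B, fx$J), rbind(c(0, 5), c(-5, 0)))
  expect_equal(giirr_C(B, fx$J), (3 * 100 / (4 * 30)) * fx$J)

  # div C = (3 delta sigma / 2N) (1, 0): here delta = 2
  expect_equal(giirr_divC(fx$target$metric_deriv(c(0, 10)), fx$J), c(1, 0))

  # constant metric: zero derivative tensor gives zero divergence
  expect_equal(giirr_divC(array(0, c(3, 3, 3)), J), c(0, 0, 0))

  # random SPD B: direct matrix arithmetic, skew-symmetry
  set.seed(8)
  for (r in 1:10) {
    B5 <- make_random_spd(runif(5, 0.5, 3), seed = r)
    J5 <- build_skew("random_pm1", 5, seed = r, norm_target = 1)
    C5 <- giirr_C(B5, J5)
    expect_equal(C5, 0.5 * (J5 %*% B5 + B5 %*% J5))
    expect_equal(C5, -t(C5))
  }
  expect_error(giirr_C(diag(3), J[1:2, 1:2]), "dimensions")
})

test_that("divergence of C matches finite differences of C on a state-dependent metric", {
  fx <- logistic_fixture()
  tg <- fx$target
  J <- build_skew("random_pm1", tg$dim, seed = 4, norm_target = 1)
  for (w in random_states(tg, 3, seed = 41)) {
    div_analytic <- giirr_divC(tg$metric_deriv(w), J)
    Cfun <- function(x) giirr_C(tg$metric(x), J)
    div_fd <- vapply(seq_len(tg$dim), function(i)
      sum(vapply(seq_len(tg$dim), function(j)
        fd_matrix_deriv(Cfun, w, j)[i, j], numeric(1))), numeric(1))
    expect_lt(rel_err(div_analytic, div_fd), 1e-4)
  }
})

test_that("drift assembly follows the five-sampler table", {
  lg <- lg_fixture()
  J <- build_skew("dense_upper_ones", 3)
  # LD drift vanishes at the posterior mode
  dd <- drift_diffusion("LD", lg$target, perturbation_spec("LD"))
  expect_equal(dd$drift(lg$posterior_mean), rep(0, 3), tolerance = 1e-12)

  # diffusion factors satisfy sigma sigma' = 2 beta B for every kind
  fx <- np_fixture()
  th <- c(1, 9)
  for (kind in c("LD", "RM", "Irr", "RMIrr", "GiIrr")) {
    pert <- perturbation_spec(kind, temperature = 0.5, skew = fx$J)
    dd <- drift_diffusion(kind, fx$target, pert)
    S <- dd$diffusion_factor(th)
    B <- if (kind %in% c("LD", "Irr")) diag(2) else fx$target$metric(th)
    expect_equal(S %*% t(S), 2 * 0.5 * B, tolerance = 1e-12)
  }

  # RMIrr drift equals an independently assembled expression from the
  # closed-form gradient and Fisher metric (dual code path)
  th <- c(5, 20)
  data <- fx$data; N <- length(data)
  m1 <- sum(data - th[1]); m2 <- sum((data - th[1])^2)
  g <- c(m1 / th[2]^2, -N / th[2] + m2 / th[2]^3)
  B <- (th[2]^2 / N) * diag(c(1, 0.5))
  expected <- drop((0.5 * B + fx$J) %*% g) + 0.5 * c(0, th[2] / N)
  dd <- drift_diffusion("RMIrr", fx$target,
                        perturbation_spec("RMIrr", skew = fx$J))
  expect_equal(dd$drift(th), expected, tolerance = 1e-12)

  # configuration errors
  metric_free <- target_model(2, function(th) -sum(th^2) / 2,
                              function(th) -th)
  expect_error(drift_diffusion("RM", metric_free, perturbation_spec("RM")),
               "metric")
  expect_error(perturbation_spec("GiIrr"), "skew")
  expect_error(perturbation_spec("Irr", skew = matrix(1, 2, 2)), "skew")
  expect_error(drift_diffusion("nope", fx$target, perturbation_spec("LD")),
               "unknown sampler kind")
})

test_that("perturbations collapse correctly in the degenerate limits", {
  fx <- np_fixture()
  states <- random_states(fx$target, 10, seed = 51)
  J0 <- matrix(0, 2, 2)

  # J = 0: GiIrr -> RM and Irr -> LD
  dd_gi0 <- drift_diffusion("GiIrr", fx$target,
                            perturbation_spec("GiIrr", skew = J0))
  dd_rm <- drift_diffusion("RM", fx$target, perturbation_spec("RM"))
  dd_irr0 <- drift_diffusion("Irr", fx$target,
                             perturbation_spec("Irr", skew = J0))
  dd_ld <- drift_diffusion("LD", fx$target, perturbation_spec("LD"))
  for (th in states) {
    expect_equal(dd_gi0$drift(th), dd_rm$drift(th))
    expect_equal(dd_irr0$drift(th), dd_ld$drift(th))
  }

  # B = I: RM -> LD, RMIrr -> Irr, GiIrr -> Irr (drift and diffusion)
  tg_id <- target_model(
    2, fx$target$log_density, fx$target$grad_log_density,
    metric = function(th) diag(2), metric_sqrt = function(th) diag(2),
    metric_div = function(th) c(0, 0),
    metric_deriv = function(th) array(0, c(2, 2, 2)),
    constant_metric = TRUE)
  for (pair in list(c("RM", "LD"), c("RMIrr", "Irr"), c("GiIrr", "Irr"))) {
    p1 <- perturbation_spec(pair[1], skew = fx$J)
    p2 <- perturbation_spec(pair[2], skew = fx$J)
    d1 <- drift_diffusion(pair[1], tg_id, p1)
    d2 <- drift_diffusion(pair[2], tg_id, p2)
    for (th in random_states(fx$target, 50, seed = 52)) {
      expect_equal(d1$drift(th), d2$drift(th))
      expect_equal(d1$diffusion_factor(th), d2$diffusion_factor(th))
    }
  }
})

test_that("constant-metric drifts are affine with matrix -(beta B + C) Gamma_p", {
  lg <- lg_fixture()
  J <- build_skew("dense_upper_ones", 3, delta = 0.7)
  B <- solve(lg$posterior_precision)
  beta <- 0.5
  mats <- list(LD = beta * diag(3), RM = beta * B,
               Irr = beta * diag(3) + J, RMIrr = beta * B + J,
               GiIrr = beta * B + giirr_C(B, J))
  set.seed(6)
  for (kind in names(mats)) {
    dd <- drift_diffusion(kind, lg$target, perturbation_spec(kind, skew = J))
    A <- mats[[kind]] %*% lg$posterior_precision
    for (r in 1:5) {
      th <- rnorm(3)
      expect_equal(dd$drift(th),
                   drop(-A %*% (th - lg$posterior_mean)), tolerance = 1e-12)
    }
  }
})

test_that("every sampler kind leaves the target density stationary (Fokker-Planck residual)", {
  skip_if_not_installed("pracma")
  fx <- np_fixture()
  tg <- fx$target
  beta <- 0.5
  xbar <- mean(fx$data)
  set.seed(42)
  states <- lapply(1:8, function(i) c(xbar + runif(1, -2, 2), runif(1, 8, 13)))
  for (kind in c("LD", "RM", "Irr", "RMIrr", "GiIrr")) {
    dd <- drift_diffusion(kind, tg, perturbation_spec(kind, skew = fx$J))
    Bfun <- if (kind %in% c("LD", "Irr")) function(th) diag(2) else tg$metric
    for (th0 in states) {
      c0 <- tg$log_density(th0)
      pi_t <- function(th) exp(tg$log_density(th) - c0)
      flux_div <- sum(diag(pracma::jacobian(
        function(th) dd$drift(th) * pi_t(th), th0)))
      diff_div <- 0
      for (i in 1:2) for (j in 1:2) {
        g <- function(th) beta * Bfun(th)[i, j] * pi_t(th)
        diff_div <- diff_div + pracma::hessian(g, th0)[i, j]
      }
      rel <- abs(diff_div - flux_div) / max(abs(flux_div), abs(diff_div))
      expect_lt(rel, 1e-3)
    }
  }
})
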