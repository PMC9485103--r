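test_that("the Euler-Maruyama step is the documented deterministic map", {
  lg <- lg_fixture()
  dd <- drift_diffusion("LD", lg$target, perturbation_spec("LD"))
  th <- c(0.4, -1, 2)
  h <- 0.01
  # zero noise: theta + h b(theta)
  expect_equal(em_step(th, dd, h, c(0, 0, 0)), th + h * dd$drift(th))
  # LD reads theta + h beta grad + sqrt(2 beta h) xi
  xi <- c(1, -2, 0.5)
  expect_equal(em_step(th, dd, h, xi),
               th + h * 0.5 * lg$target$grad_log_density(th) +
                 sqrt(2 * 0.5 * h) * xi)
})

test_that("one-step increments have covariance 2 beta h B", {
  fx <- np_fixture()
  dd <- drift_diffusion("RM", fx$target, perturbation_spec("RM"))
  th <- c(1, 9); h <- 1e-3
  set.seed(13)
  n_rep <- 2e4
  xi <- matrix(rnorm(2 * n_rep), ncol = 2)
  inc <- t(apply(xi, 1, function(z) em_step(th, dd, h, z) - th - h * dd$drift(th)))
  emp <- crossprod(inc) / n_rep
  expect_equal(emp, 2 * 0.5 * h * fx$target$metric(th),
               tolerance = 0.05)  # Monte-Carlo error at 2e4 draws
})

test_that("stochastic gradients are exact at n = N and unbiased otherwise", {
  tg <- normal_params_model(c(2, -1, 0.5))
  th <- c(0.3, 1.2)
  # n = N without replacement: full gradient exactly
  set.seed(1)
  expect_identical(stochastic_gradient(tg, th, 3),
                   tg$grad_log_density(th))
  # forced tau = {2}, N = 3: prior + 3 * datum_grad(theta, 2)
  expect_equal(stochastic_gradient(tg, th, 1, indices = 2L),
               tg$prior_grad(th) + 3 * tg$datum_grad(th, 2))
  expect_error(stochastic_gradient(tg, th, 4), "1 <= n <= N")

  # unbiasedness: componentwise z-test over independent draws
  fx <- np_fixture()
  th <- c(1, 8)
  full <- fx$target$grad_log_density(th)
  set.seed(2)
  draws <- t(replicate(1e4, stochastic_gradient(fx$target, th, 6)))
  z <- (colMeans(draws) - full) / (apply(draws, 2, sd) / sqrt(nrow(draws)))
  expect_true(all(abs(z) < 4))
})

test_that("minibatch schemes draw uniformly without replacement", {
  # subset-table scheme: each datum appears with frequency n/N
  scheme <- giirr:::minibatch_scheme(10, 3, FALSE)
  expect_equal(scheme$type, "subset_table")
  set.seed(3)
  ids <- giirr:::draw_minibatch_ids(scheme, 6000)
  counts <- tabulate(as.vector(scheme$table[, ids[, 1]]), 10)
  expect_equal(counts / sum(counts), rep(0.1, 10), tolerance = 0.05)
  idx <- giirr:::minibatch_indices(scheme, ids, 1)
  expect_length(unique(idx), 3)

  # large choose(N, n) falls back to per-step sample.int
  scheme2 <- giirr:::minibatch_scheme(400, 40, FALSE)
  expect_equal(scheme2$type, "sample_int")

  scheme3 <- giirr:::minibatch_scheme(10, 3, TRUE)
  expect_equal(scheme3$type, "replacement")
  ids3 <- giirr:::draw_minibatch_ids(scheme3, 50)
  expect_true(all(ids3 >= 1 & ids3 <= 10))
})

test_that("chains are deterministic, nest across ensemble sizes, and respect K = 0", {
  fx <- np_fixture()
  pert <- perturbation_spec("GiIrr", skew = fx$J)
  cfg <- sampler_config(1e-3, 200, seed = 5, minibatch_size = 6,
                        initial_state = c(5, 20))

  # K = 0 holds only the initial state
  cfg0 <- sampler_config(1e-3, 0, seed = 5, initial_state = c(5, 20))
  ch0 <- run_chain(fx$target, pert, cfg0)
  expect_equal(nrow(ch0$states), 1L)
  expect_equal(nrow(ch0$observable_values), 0L)

  # identical seeds give identical trajectories
  ch1 <- run_chain(fx$target, pert, cfg)
  ch2 <- run_chain(fx$target, pert, cfg)
  expect_identical(ch1$states, ch2$states)

  # ensembles nest: first chains of a larger ensemble equal the smaller's
  e2 <- run_ensemble(fx$target, pert, cfg, n_chains = 2, base_seed = 17)
  e4 <- run_ensemble(fx$target, pert, cfg, n_chains = 4, base_seed = 17)
  expect_identical(e2$chains[[1]]$states, e4$chains[[1]]$states)
  expect_identical(e2$chains[[2]]$states, e4$chains[[2]]$states)
  expect_false(identical(e4$chains[[3]]$states, e4$chains[[4]]$states))

  # first-step increments are uncorrelated across chains
  cfg1 <- sampler_config(1e-3, 1, seed = 5, initial_state = c(5, 20))
  e <- run_ensemble(fx$target, perturbation_spec("LD"), cfg1,
                    n_chains = 100, base_seed = 23)
  inc <- t(vapply(e$chains, function(ch) ch$final_state - c(5, 20),
                  numeric(2)))
  expect_lt(abs(cor(inc[seq(1, 99, 2), 1], inc[seq(2, 100, 2), 1])), 0.25)

  # thinning keeps estimator inputs intact
  cfg_thin <- sampler_config(1e-3, 200, seed = 5, minibatch_size = 6,
                             initial_state = c(5, 20), thin = 50)
  ch_thin <- run_chain(fx$target, pert, cfg_thin)
  expect_equal(nrow(ch_thin$states), 5L)   # steps 0, 50, 100, 150, 200
  expect_identical(ch_thin$observable_values, ch1$observable_values)
  expect_equal(ch_thin$states[2, ], ch1$states[51, ])
})

test_that("the generic stepper matches the closed linear-Gaussian recurrence", {
  lg <- lg_fixture()
  cfg <- sampler_config(0.005, 150, seed = 31, initial_state = rep(0, 3))
  ch <- run_chain(lg$target, perturbation_spec("LD"), cfg)

  # independent path: theta' = (I - A h) theta + D h + sqrt(h) xi with the
  # same noise stream
  streams <- giirr:::chain_streams(cfg$seed, 1)[[1]]
  xi <- matrix(giirr:::draw_stream(streams$noise,
                                   function() rnorm(150 * 3))$value,
               nrow = 150, byrow = TRUE)
  th <- rep(0, 3)
  A <- lg$drift_matrix; D <- lg$drift_offset; h <- 0.005
  for (k in 1:150) th <- drop((diag(3) - A * h) %*% th) + D * h +
      sqrt(h) * xi[k, ]
  expect_equal(ch$final_state, th, tolerance = 1e-12)
})

test_that("compiled kernels reproduce the generic stepper bit-for-bit", {
  fx <- np_fixture()
  cfg_sg <- sampler_config(1e-3, 300, seed = 7, minibatch_size = 6,
                           initial_state = c(5, 20))
  cfg_ex <- sampler_config(1e-3, 300, seed = 7, initial_state = c(5, 20))
  for (kind in c("LD", "RM", "Irr", "RMIrr", "GiIrr")) {
    pert <- perturbation_spec(kind, skew = fx$J)
    for (cfg in list(cfg_sg, cfg_ex)) {
      ch <- run_chain(fx$target, pert, cfg)
      fast <- giirr:::run_chain_np(fx$data, kind, cfg, delta = 2)
      expect_equal(unname(ch$observable_values[, "phi1"]), fast$phi1,
                   tolerance = 1e-10)
      expect_equal(ch$final_state, fast$final_state, tolerance = 1e-10)
    }
  }

  lg <- lg_fixture()
  J3 <- build_skew("dense_upper_ones", 3)
  cfg <- sampler_config(0.005, 300, seed = 9, minibatch_size = 2,
                        initial_state = rep(0, 3))
  for (kind in c("LD", "RM", "Irr", "RMIrr", "GiIrr")) {
    ch <- run_chain(lg$target, perturbation_spec(kind, skew = J3), cfg)
    fast <- giirr:::run_chain_lg(lg, kind, cfg, J = J3)
    expect_equal(unname(ch$observable_values[, "phi1"]), fast$phi1,
                 tolerance = 1e-10)
  }

  fx_ica <- ica_fixture()
  J9 <- build_skew("kronecker", 9, norm_target = 1)
  C0 <- build_skew("dense_upper_ones", 3)
  raw <- kronecker(diag(3), C0) + kronecker(C0, diag(3))
  C0 <- C0 / norm(raw, "2")
  cfg <- sampler_config(1e-4, 150, seed = 11, minibatch_size = 10,
                        initial_state = as.vector(diag(c(1, -1, 1))))
  for (kind in c("LD", "RM", "Irr", "RMIrr", "GiIrr")) {
    ch <- run_chain(fx_ica$target, perturbation_spec(kind, skew = J9), cfg)
    fast <- giirr:::run_chain_ica(fx_ica$data$X, kind, cfg, C0 = C0)
    expect_equal(unname(ch$observable_values[, "phi1"]), fast$phi1,
                 tolerance = 1e-10)
    expect_equal(ch$final_state, fast$final_state, tolerance = 1e-10)
  }
})

test_that("long chains reach the discrete-time stationary law", {
  # 1-D Gaussian, precision 1, beta = 1/2, h = 0.01: empirical variance of a
  # 1e6-step chain matches the discrete Lyapunov oracle
  lg1 <- gaussian_posterior(matrix(0.5), matrix(0.05), matrix(0, 10, 1))
  expect_equal(drop(lg1$posterior_precision), 1)
  law <- em_stationary_law(0.5 * lg1$posterior_precision, h = 0.01)
  cfg <- sampler_config(0.01, 1e6, seed = 3, initial_state = 0)
  fast <- giirr:::run_chain_lg(lg1, "LD", cfg)
  emp_var <- var(fast$phi1[-(1:5000)])
  # 3 standard errors of a variance estimate with autocorrelation time
  # tau ~ 2/(h a) steps
  se <- drop(law$covariance) * sqrt(2 * (2 / (0.01 * 0.5)) / 1e6)
  expect_lt(abs(emp_var - drop(law$covariance)), 3 * se)
})

test_that("irreversible perturbations break detailed balance (rotational flux)", {
  # isotropic 2-D Gaussian: the mean rotational flux theta1 dtheta2 -
  # theta2 dtheta1 vanishes for LD and not for Irr
  lg <- gaussian_posterior(diag(2), 0.1 * diag(2), matrix(0, 10, 2))
  J <- build_skew("dense_upper_ones", 2, delta = 1)
  cfg <- sampler_config(0.01, 2e5, seed = 19, initial_state = c(0, 0))
  flux <- function(kind) {
    res <- giirr:::run_chain_lg(lg, kind, cfg, J = J, store_states = TRUE)
    s <- res$states
    x1 <- s[-nrow(s), 1]; y1 <- s[-nrow(s), 2]
    x2 <- s[-1, 1]; y2 <- s[-1, 2]
    f <- x1 * y2 - y1 * x2
    mean(f) / (sd(f) / sqrt(length(f)))
  }
  expect_lt(abs(flux("LD")), 4)    # consistent with zero
  expect_gt(abs(flux("Irr")), 10)  # decisively nonzero
})
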