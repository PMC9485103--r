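# Shared oracles and fixtures, built in code.

# central finite difference of a scalar function
fd_grad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h * max(1, abs(x[i]))
    (f(x + e) - f(x - e)) / (2 * e[i])
  }, numeric(1))
}

# central finite difference of a matrix-valued function: d/dx_k F(x)
fd_matrix_deriv <- function(F, x, k, h = 1e-5) {
  e <- numeric(length(x)); e[k] <- h * max(1, abs(x[k]))
  (F(x + e) - F(x - e)) / (2 * e[k])
}

rel_err <- function(a, b) {
  denom <- max(abs(a), abs(b), 1e-10)
  max(abs(a - b)) / denom
}

# small seeded fixtures
np_fixture <- function(seed = 3) {
  data <- gen_normal_data(30, 0, 10, seed = seed)
  list(data = data, target = normal_params_model(data),
       J = build_skew("dense_upper_ones", 2, delta = 2))
}

logistic_fixture <- function(N = 40, d = 4, seed = 5) {
  dat <- gen_logistic_data(N, d, seed = seed)
  list(data = dat,
       target = logistic_model(dat$features, dat$labels, alpha = 1))
}

ica_fixture <- function(N = 30, seed = 7) {
  dat <- gen_ica_data(3, N, mixing_seed = seed, source_seed = seed + 1)
  list(data = dat, target = ica_model(dat$X, lambda = 1))
}

lg_fixture <- function(d = 3, N = 10, seed = 2) {
  prior <- make_random_spd(rep(0.1, d) + seq_len(d) / 10, seed = seed)
  set.seed(seed + 1)
  data <- matrix(rnorm(N * d, sd = 2), N, d)
  gaussian_posterior(prior, 0.25 * diag(d), data)
}

# random admissible states near each target's posterior bulk
random_states <- function(target, n, seed = 1) {
  set.seed(seed)
  switch(target$name,
    normal_params = lapply(seq_len(n), function(i)
      c(runif(1, -4, 4), runif(1, 5, 15))),
    logistic = lapply(seq_len(n), function(i)
      rnorm(target$dim, sd = 0.5)),
    ica = lapply(seq_len(n), function(i) {
      repeat {
        w <- rnorm(target$dim, sd = 0.6)
        if (abs(det(matrix(w, sqrt(target$dim)))) > 0.1) return(w)
      }
    }),
    lapply(seq_len(n), function(i) rnorm(target$dim)))
}
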