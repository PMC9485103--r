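## Experiment presets and synthetic data.
##
## Each preset records the study conditions of one worked example -- sample
## sizes, step size, chain count, skew pattern, burn-in, initial state --
## with the reference values as defaults, plus scale overrides for desk-size
## runs. Data are generated synthetically from seeded generators, so every
## experiment is reproducible from a single base seed.

PRESET_NAMES <- c("gaussian", "normal_params", "logistic", "ica")

#' Random SPD matrix with a prescribed spectrum
#'
#' `Q diag(eigenvalues) Q'` with Q a seeded random orthogonal matrix
#' (QR-orthogonalized Gaussian with positive-diagonal sign convention).
#'
#' @param eigenvalues Positive eigenvalues.
#' @param seed Seed for the random eigenvectors.
#' @return SPD matrix with the requested spectrum.
#' @export
make_random_spd <- function(eigenvalues, seed = 1L) {
  if (any(eigenvalues <= 0))
    stop("all eigenvalues must be positive", call. = FALSE)
  d <- length(eigenvalues)
  G <- matrix(draw_stream(make_streams(seed, 1L)[[1L]],
                          function() rnorm(d * d))$value, d, d)
  qr_ <- qr(G)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), d)
  Q %*% (eigenvalues * t(Q))
}

#' Synthetic normal sample
#'
#' @param N Sample size.
#' @param mu_true,sigma_true True mean and standard deviation
#'   (`sigma_true > 0`).
#' @param seed Seed.
#' @return Numeric vector of N draws.
#' @export
gen_normal_data <- function(N = 30L, mu_true = 0, sigma_true = 10,
                            seed = 1L) {
  if (sigma_true <= 0) stop("`sigma_true` must be positive", call. = FALSE)
  draw_stream(make_streams(seed, 1L)[[1L]],
              function() rnorm(N, mu_true, sigma_true))$value
}

#' Synthetic logistic-regression data
#'
#' Standard-normal feature rows and Bernoulli labels with success
#' probability `plogis(x' w_true)` -- a stand-in with the same layout as the
#' benchmark credit-scoring table (features plus a 0/1 label).
#'
#' @param N,d Numbers of observations and features.
#' @param w_true True weight vector (default: seeded standard normal).
#' @param seed Seed.
#' @return List with `features` (N x d) and `labels` (length N).
#' @export
gen_logistic_data <- function(N = 400L, d = 20L, w_true = NULL, seed = 1L) {
  draw <- draw_stream(make_streams(seed, 1L)[[1L]], function() {
    w <- if (is.null(w_true)) rnorm(d) else w_true
    X <- matrix(rnorm(N * d), N, d)
    t_ <- as.numeric(runif(N) < stats::plogis(drop(X %*% w)))
    list(features = X, labels = t_, w_true = w)
  })
  draw$value
}

#' Synthetic mixed independent sources
#'
#' Generates m independent source signals -- one standard Laplace and
#' `m - 1` with the `(1/4) sech^2(y/2)` density (the standard logistic law,
#' drawn via its inverse CDF `y = logit(u)`) -- and mixes them with a seeded
#' random matrix with condition number at most 10, so `X = M s` exactly.
#'
#' @param m Number of channels (>= 2).
#' @param N Number of time instances.
#' @param mixing_seed,source_seed Seeds for the mixing matrix and sources.
#' @return List with `X` (m x N mixed signals), `mixing` (m x m), and
#'   `sources` (m x N).
#' @export
gen_ica_data <- function(m = 3L, N = 400L, mixing_seed = 1L,
                         source_seed = 2L) {
  if (m < 2) stop("`m` must be at least 2", call. = FALSE)
  mixing <- draw_stream(make_streams(mixing_seed, 1L)[[1L]], function() {
    repeat {
      M <- matrix(rnorm(m * m), m, m)
      if (kappa(M, exact = TRUE) <= 10) return(M)
    }
  })$value
  sources <- draw_stream(make_streams(source_seed, 1L)[[1L]], function() {
    u <- matrix(runif(m * N), m, N)
    s <- stats::qlogis(u)                      # sech^2 sources
    s[1L, ] <- ifelse(u[1L, ] < 0.5,           # Laplace source
                      log(2 * u[1L, ]), -log(2 * (1 - u[1L, ])))
    s
  })$value
  list(X = mixing %*% sources, mixing = mixing, sources = sources)
}

#' Experiment preset
#'
#' Bundles the study conditions of one worked example. Defaults follow the
#' reference studies: `gaussian` (d = 3, N = 10, n = 2, Gamma_X = 0.25 I,
#' prior eigenvalues 0.2/0.01/0.05, h = 0.005, K = 1e5, zero start, no
#' burn-in, delta = 1); `normal_params` (N = 30, n = 6, h = 1e-3, K = 1e6,
#' delta = 2, burn-in time 10, start (5, 20), data from N(0, 10^2));
#' `logistic` (d = 20, N = 400, n = 10, h = 1e-4, K = 4e5, zero start,
#' random +/-1 skew of unit spectral norm, alpha = 1); `ica` (m = 3, N =
#' 400, n = 40, Kronecker skew of unit norm, lambda = 1; the default run is
#' scaled down to T = 20 at h = 1e-4 with 10 chains -- set
#' `paper_scale = TRUE` for T = 2000 at h = 2e-5 with 100 chains).
#'
#' @param name One of `"gaussian"`, `"normal_params"`, `"logistic"`,
#'   `"ica"`.
#' @param ... Named overrides of preset fields (e.g. `n_chains`, `n_steps`,
#'   `use_sg`); unknown names are an error.
#' @param paper_scale Use the full-scale ICA settings.
#' @return An object of class `experiment_preset`.
#' @export
experiment_preset <- function(name = PRESET_NAMES, ..., paper_scale = FALSE) {
  name <- match.arg(name)
  p <- switch(name,
    gaussian = list(
      name = "gaussian", d = 3L, N = 10L, minibatch_size = 2L,
      h = 0.005, n_steps = 1e5, n_chains = 1000L, burn_in_steps = 0L,
      beta = 0.5, delta = 1,
      initial_state = rep(0, 3L),
      skew = list(pattern = "dense_upper_ones"),
      noise_precision_scale = 0.25,
      prior_eigenvalues = c(0.2, 0.01, 0.05),
      eigenvector_seed = 1L, data_seed = 2L, use_sg = TRUE),
    normal_params = list(
      name = "normal_params", d = 2L, N = 30L, minibatch_size = 6L,
      h = 1e-3, n_steps = 1e6, n_chains = 1000L, burn_in_time = 10,
      beta = 0.5, delta = 2,
      initial_state = c(5, 20),
      skew = list(pattern = "dense_upper_ones"),
      mu_true = 0, sigma_true = 10, data_seed = 2L, use_sg = TRUE),
    logistic = list(
      name = "logistic", d = 20L, N = 400L, minibatch_size = 10L,
      h = 1e-4, n_steps = 4e5, n_chains = 100L, burn_in_steps = 4e4,
      beta = 0.5, delta = 1, alpha = 1,
      initial_state = rep(0, 20L),
      skew = list(pattern = "random_pm1", norm_target = 1, seed = 3L),
      data_seed = 2L, use_sg = TRUE),
    ica = if (paper_scale) list(
      name = "ica", m = 3L, d = 9L, N = 400L, minibatch_size = 40L,
      h = 2e-5, n_steps = 1e8, n_chains = 100L, burn_in_time = 20,
      beta = 0.5, delta = 1, lambda = 1,
      skew = list(pattern = "kronecker", norm_target = 1),
      init_seed = 4L, mixing_seed = 1L, source_seed = 2L, use_sg = TRUE)
    else list(
      name = "ica", m = 3L, d = 9L, N = 400L, minibatch_size = 40L,
      h = 1e-4, n_steps = 2e5, n_chains = 10L, burn_in_time = 2,
      beta = 0.5, delta = 1, lambda = 1,
      skew = list(pattern = "kronecker", norm_target = 1),
      init_seed = 4L, mixing_seed = 1L, source_seed = 2L, use_sg = TRUE))
  if (is.null(p$burn_in_steps))
    p$burn_in_steps <- as.integer(round(p$burn_in_time / p$h))
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), c(names(p), "burn_in_time"))
    if (length(bad))
      stop(sprintf("unknown preset field(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    p <- utils::modifyList(p, overrides)
    ## burn-in is specified in time units; recompute the step count when the
    ## time or the step size changes, unless steps were pinned explicitly
    if (!is.null(p$burn_in_time) && !("burn_in_steps" %in% names(overrides)))
      p$burn_in_steps <- as.integer(round(p$burn_in_time / p$h))
  }
  p$n_steps <- as.integer(p$n_steps)
  p$n_chains <- as.integer(p$n_chains)
  p$burn_in_steps <- as.integer(p$burn_in_steps)
  structure(p, class = "experiment_preset")
}

#' @export
print.experiment_preset <- function(x, ...) {
  cat(sprintf("<experiment_preset> %s: d = %d, N = %d, K = %g, h = %g, M = %d\n",
              x$name, x$d, x$N, x$n_steps, x$h, x$n_chains))
  invisible(x)
}

## Build the target and skew matrix of a preset (data generated from the
## preset's seeds, themselves derived from base_seed unless fixed).
build_preset_problem <- function(preset, base_seed = 1L) {
  ds <- base_seed + preset$data_seed
  switch(preset$name,
    gaussian = {
      prior <- make_random_spd(preset$prior_eigenvalues,
                               seed = base_seed + preset$eigenvector_seed)
      noise_prec <- preset$noise_precision_scale * diag(preset$d)
      ## observations X_i ~ N(0, Gamma_X^-1) around a zero truth
      data <- matrix(draw_stream(make_streams(ds, 1L)[[1L]], function()
        rnorm(preset$N * preset$d, sd = sqrt(1 / preset$noise_precision_scale)))$value,
        preset$N, preset$d)
      lg <- gaussian_posterior(prior, noise_prec, data)
      J <- build_skew("dense_upper_ones", preset$d, delta = preset$delta)
      list(target = lg$target, lg = lg, J = J)
    },
    normal_params = {
      data <- gen_normal_data(preset$N, preset$mu_true, preset$sigma_true,
                              seed = ds)
      J <- build_skew("dense_upper_ones", 2L, delta = preset$delta)
      list(target = normal_params_model(data), data = data, J = J)
    },
    logistic = {
      dat <- gen_logistic_data(preset$N, preset$d, seed = ds)
      J <- build_skew("random_pm1", preset$d, seed = preset$skew$seed,
                      norm_target = preset$skew$norm_target)
      list(target = logistic_model(dat$features, dat$labels, preset$alpha),
           data = dat, J = J)
    },
    ica = {
      dat <- gen_ica_data(preset$m, preset$N,
                          mixing_seed = base_seed + preset$mixing_seed,
                          source_seed = base_seed + preset$source_seed)
      J <- build_skew("kronecker", preset$d,
                      norm_target = preset$skew$norm_target)
      ## m x m generator of J carrying the same rescaling (fast-path input)
      C0 <- build_skew("dense_upper_ones", preset$m)
      raw <- kronecker(diag(preset$m), C0) + kronecker(C0, diag(preset$m))
      C0 <- C0 * (preset$skew$norm_target / norm(raw, "2"))
      init <- draw_stream(make_streams(base_seed + preset$init_seed, 1L)[[1L]],
                          function() sample(c(-1, 1), preset$m,
                                            replace = TRUE))$value
      list(target = ica_model(dat$X, preset$lambda), data = dat, J = J,
           C0 = C0, initial_state = as.vector(diag(init, preset$m)))
    })
}

preset_config <- function(preset, problem) {
  init <- if (!is.null(preset$initial_state)) preset$initial_state else
    problem$initial_state
  sampler_config(
    step_size = preset$h, n_steps = preset$n_steps,
    burn_in_steps = preset$burn_in_steps,
    minibatch_size = if (isTRUE(preset$use_sg)) preset$minibatch_size,
    initial_state = init)
}

preset_observables <- function(preset) {
  obs <- default_observables(preset$d)
  if (preset$name == "ica")
    obs$phi3 <- function(state) sum(state)^2
  obs
}

#' Run a preset experiment across sampler kinds
#'
#' For each requested kind: builds the preset's target, data, and skew
#' matrix, runs the ensemble of chains (through the compiled fast path for
#' the `gaussian` and `normal_params` presets, the generic stepper
#' otherwise), and computes the per-chain batch-means asymptotic variance of
#' each observable plus optional running-average curves. Chain failures
#' (e.g. a singular de-mixing matrix) are collected per kind; the run
#' aborts only if more than 10 percent of a kind's chains fail.
#'
#' @param preset An [experiment_preset()] (or preset name).
#' @param kinds Character vector of sampler kinds (default: all five).
#' @param base_seed Seed for data generation and all chain streams.
#' @param n_batches Batches for the asymptotic-variance estimate.
#' @param curve_points Optional chain lengths at which running-average
#'   curves are recorded (stored in `$curves`).
#' @param reference Optional named list of reference expectations per
#'   observable for bias curves.
#' @param ... Overrides forwarded to [experiment_preset()] when `preset` is
#'   given by name.
#' @return An object of class `metrics_report`; see [tidy.metrics_report()].
#' @export
run_experiment <- function(preset, kinds = KINDS, base_seed = 1L,
                           n_batches = 20L, curve_points = NULL,
                           reference = NULL, ...) {
  if (is.character(preset)) preset <- experiment_preset(preset, ...)
  kinds <- vapply(kinds, match_kind, character(1))
  problem <- build_preset_problem(preset, base_seed)
  config <- preset_config(preset, problem)
  if (preset$name == "normal_params" && !is.null(config$minibatch_size)) {
    problem$np_scheme <- minibatch_scheme(preset$N, config$minibatch_size,
                                          config$with_replacement)
    problem$np_tables <- np_subset_tables(problem$data, problem$np_scheme)
  }
  observables <- preset_observables(preset)
  obs_names <- names(observables)

  avar_rows <- list()
  curve_rows <- list()
  warnings <- character(0)

  for (kind in kinds) {
    pert <- perturbation_spec(kind, temperature = preset$beta,
                              skew = problem$J, scale = preset$delta)
    streams <- chain_streams(base_seed, preset$n_chains)
    per_chain <- vector("list", preset$n_chains)
    failed <- logical(preset$n_chains)
    for (i in seq_len(preset$n_chains)) {
      res <- tryCatch(
        run_preset_chain(preset, problem, kind, config, observables,
                         streams[[i]]),
        error = function(e) e)
      if (inherits(res, "error")) {
        failed[i] <- TRUE
        warnings <- c(warnings,
                      sprintf("%s chain %d failed: %s", kind, i,
                              conditionMessage(res)))
      } else per_chain[[i]] <- res
    }
    n_failed <- sum(failed)
    if (n_failed > 0.1 * preset$n_chains)
      stop(sprintf("more than 10%% of %s chains failed (%d of %d)",
                   kind, n_failed, preset$n_chains), call. = FALSE)
    ok <- per_chain[!failed]

    if (config$n_steps > 0L && length(ok)) {
      avar <- sapply(obs_names, function(nm)
        vapply(ok, function(ch)
          batch_means_avar(ch[[nm]], preset$h, preset$burn_in_steps,
                           n_batches), numeric(1)))
      avar <- matrix(avar, nrow = length(ok),
                     dimnames = list(NULL, obs_names))
      for (nm in obs_names)
        avar_rows[[length(avar_rows) + 1L]] <- tibble::tibble(
          kind = kind, observable = nm,
          avar_mean = mean(avar[, nm]), avar_std = stats::sd(avar[, nm]),
          n_chains = length(ok), n_failed = n_failed)
    } else {
      for (nm in obs_names)
        avar_rows[[length(avar_rows) + 1L]] <- tibble::tibble(
          kind = kind, observable = nm, avar_mean = NA_real_,
          avar_std = NA_real_, n_chains = length(ok), n_failed = n_failed)
    }

    if (!is.null(curve_points) && length(ok)) {
      pts <- sort(unique(pmin(as.integer(curve_points), config$n_steps)))
      pts <- pts[pts >= 1L]
      for (nm in obs_names) {
        ra <- vapply(ok, function(ch) running_average(ch[[nm]])[pts],
                     numeric(length(pts)))
        ra <- matrix(ra, nrow = length(pts))
        curve <- tibble::tibble(
          kind = kind, observable = nm, K = pts,
          mean_running_average = rowMeans(ra),
          variance = rowMeans(ra^2) - rowMeans(ra)^2)
        if (!is.null(reference[[nm]])) {
          curve$bias <- curve$mean_running_average - reference[[nm]]
          curve$mse <- curve$bias^2 + curve$variance
        }
        curve_rows[[length(curve_rows) + 1L]] <- curve
      }
    }
  }

  structure(list(
    avar = dplyr::bind_rows(avar_rows),
    curves = if (length(curve_rows)) dplyr::bind_rows(curve_rows),
    provenance = list(
      preset = unclass(preset), kinds = kinds, base_seed = base_seed,
      n_batches = n_batches, warnings = warnings,
      package_version = as.character(utils::packageVersion("giirr")))),
    class = "metrics_report")
}

## One chain of a preset: fast path where available, generic stepper
## otherwise. Returns a named list of per-step observable series.
run_preset_chain <- function(preset, problem, kind, config, observables,
                             streams) {
  if (preset$name == "normal_params") {
    res <- run_chain_np(problem$data, kind, config, delta = preset$delta,
                        beta = preset$beta, streams = streams,
                        tables = problem$np_tables,
                        scheme = problem$np_scheme)
    list(phi1 = res$phi1, phi2 = res$phi2)
  } else if (preset$name == "gaussian") {
    res <- run_chain_lg(problem$lg, kind, config, J = problem$J,
                        beta = preset$beta, streams = streams)
    list(phi1 = res$phi1, phi2 = res$phi2)
  } else if (preset$name == "ica") {
    res <- run_chain_ica(problem$data$X, kind, config, C0 = problem$C0,
                         lambda = preset$lambda, beta = preset$beta,
                         streams = streams)
    list(phi1 = res$phi1, phi2 = res$phi2, phi3 = res$phi3)
  } else {
    pert <- perturbation_spec(kind, temperature = preset$beta,
                              skew = problem$J, scale = preset$delta)
    chain <- run_chain(problem$target, pert,
                       modifyList(config, list(thin = config$n_steps + 1L)),
                       observables, streams = streams)
    out <- lapply(seq_along(observables),
                  function(j) chain$observable_values[, j])
    names(out) <- names(observables)
    out
  }
}

#' @describeIn run_experiment Tidy the asymptotic-variance table.
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) x$avar

#' @describeIn run_experiment One-row summary: preset, kinds, and the kind
#'   with the smallest `phi1` asymptotic variance.
#' @export
glance.metrics_report <- function(x, ...) {
  phi1 <- dplyr::filter(x$avar, .data$observable == "phi1")
  tibble::tibble(
    preset = x$provenance$preset$name,
    n_kinds = length(unique(x$avar$kind)),
    n_chains = max(x$avar$n_chains),
    best_kind = if (nrow(phi1) && !all(is.na(phi1$avar_mean)))
      phi1$kind[which.min(phi1$avar_mean)] else NA_character_)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> preset = %s, base_seed = %d\n",
              x$provenance$preset$name, x$provenance$base_seed))
  print(x$avar)
  invisible(x)
}

#' @describeIn run_experiment Plot asymptotic variances by sampler kind.
#' @param object A `metrics_report`.
#' @export
autoplot.metrics_report <- function(object, ...) {
  df <- dplyr::mutate(object$avar,
                      kind = factor(.data$kind, levels = KINDS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$avar_mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$avar_mean - .data$avar_std, 0),
      ymax = .data$avar_mean + .data$avar_std)) +
    ggplot2::facet_wrap(~observable, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "asymptotic variance (batch means)")
}

#' @describeIn ksd Plot the running KSD curve on log-log axes with a
#'   reference slope of -1/2.
#' @param object A `ksd_result`.
#' @export
autoplot.ksd_result <- function(object, ...) {
  curve <- object$curve
  anchor <- curve$value[1L] * sqrt(curve$K[1L])
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$K, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = anchor / sqrt(.data$K)),
                       linetype = "dashed") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "K", y = "KSD")
}
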