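## Euler-Maruyama integration.
##
## The stepping rule is theta' = theta + h b(theta) + sqrt(h) sigma(theta) xi
## with unit-variance Gaussian noise xi, so that for plain Langevin dynamics
## (sigma = sqrt(2 beta) I) it reads theta + h beta grad log pi + sqrt(2 beta
## h) xi. Observables are recorded at theta_0, ..., theta_{K-1}, matching the
## long-term-average estimator (1/K) sum_{k=0}^{K-1} f(theta_k).

#' Sampler configuration
#'
#' @param step_size Step size h > 0.
#' @param n_steps Number of steps K (>= 0).
#' @param burn_in_steps Steps discarded by downstream estimators (< K unless
#'   K = 0); the chain itself always records everything.
#' @param seed Base seed used when the chain is run standalone.
#' @param minibatch_size Optional subsample size n <= N; `NULL` (default)
#'   uses the full gradient.
#' @param with_replacement Draw minibatch indices with replacement
#'   (default `FALSE`).
#' @param initial_state Initial state vector.
#' @param thin Keep every `thin`-th state (observables are always recorded
#'   at every step, so estimators are unaffected).
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(step_size, n_steps, burn_in_steps = 0L, seed = 1L,
                           minibatch_size = NULL, with_replacement = FALSE,
                           initial_state, thin = 1L) {
  stopifnot(is.numeric(step_size), step_size > 0,
            is.numeric(n_steps), n_steps >= 0,
            is.numeric(burn_in_steps), burn_in_steps >= 0,
            is.numeric(thin), thin >= 1)
  if (n_steps > 0 && burn_in_steps >= n_steps)
    stop("`burn_in_steps` must be smaller than `n_steps`", call. = FALSE)
  structure(list(step_size = step_size, n_steps = as.integer(n_steps),
                 burn_in_steps = as.integer(burn_in_steps),
                 seed = as.integer(seed),
                 minibatch_size = if (is.null(minibatch_size)) NULL else
                   as.integer(minibatch_size),
                 with_replacement = isTRUE(with_replacement),
                 initial_state = as.numeric(initial_state),
                 thin = as.integer(thin)),
            class = "sampler_config")
}

config_digest <- function(config) {
  flat <- config[order(names(config))]
  json <- jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp)
  unname(tools::md5sum(tmp))
}

#' One Euler-Maruyama step
#'
#' `theta' = theta + h * b(theta) + sqrt(h) * sigma(theta) %*% noise`, with
#' externally supplied unit-variance noise so the stepping rule is
#' deterministic given its inputs.
#'
#' @param state Current state vector.
#' @param dd A [drift_diffusion()].
#' @param h Step size.
#' @param noise d-vector of unit-variance innovations.
#' @param grad Optional pre-computed gradient estimate passed to the drift.
#' @return The next state.
#' @export
em_step <- function(state, dd, h, noise, grad = NULL) {
  b <- dd$drift(state, grad)
  if (!all(is.finite(b)))
    stop_numerical("non-finite drift in em_step", state = state)
  out <- state + h * b + sqrt(h) * drop(dd$diffusion_factor(state) %*% noise)
  if (!all(is.finite(out)))
    stop_numerical("non-finite state in em_step", state = out)
  out
}

#' Stochastic-gradient estimate of the log-posterior gradient
#'
#' `prior_grad(theta) + (N/n) * sum_{i in tau} datum_grad(theta, i)` with a
#' fresh uniformly random index set `tau` of size n per call (without
#' replacement by default). With `n = N` and `with_replacement = FALSE` the
#' full gradient is recovered exactly.
#'
#' @param target A [target_model()] with per-datum gradients.
#' @param state State vector.
#' @param n Subsample size, `1 <= n <= N`.
#' @param with_replacement Logical.
#' @param indices Optional explicit index set (overrides the random draw).
#' @return Gradient estimate (d-vector).
#' @export
stochastic_gradient <- function(target, state, n, with_replacement = FALSE,
                                indices = NULL) {
  N <- target$n_data
  if (n > N || n < 1)
    stop("minibatch size must satisfy 1 <= n <= N", call. = FALSE)
  if (is.null(indices)) {
    indices <- if (with_replacement)
      sample.int(N, n, replace = TRUE) else sample.int(N, n)
  }
  if (!is.null(target$minibatch_grad))
    return(target$minibatch_grad(state, indices))
  acc <- target$prior_grad(state)
  for (i in indices) acc <- acc + (N / n) * target$datum_grad(state, i)
  ## note: scaling inside the loop keeps exactness when n = N
  acc
}

## ---------------------------------------------------------------------------
## Minibatch index plumbing.
##
## Uniform subsets without replacement are drawn as a single uniform variate
## indexing the enumerated table of all choose(N, n) subsets whenever that
## table is small enough; otherwise per-step sample.int. Both schemes are
## exactly uniform over n-subsets; the table scheme costs one variate per
## step, which keeps million-step chains cheap and lets the compiled fast
## paths replay identical index sequences.

MAX_SUBSET_TABLE <- 1e6

minibatch_scheme <- function(N, n, with_replacement) {
  if (is.null(n)) return(list(type = "none"))
  if (n > N) stop("minibatch size exceeds the number of data points",
                  call. = FALSE)
  if (with_replacement)
    return(list(type = "replacement", N = N, n = n))
  n_subsets <- choose(N, n)
  if (n_subsets <= MAX_SUBSET_TABLE && n_subsets > 1) {
    list(type = "subset_table", N = N, n = n,
         table = utils::combn(N, n), n_subsets = n_subsets)
  } else {
    list(type = "sample_int", N = N, n = n)
  }
}

## Draw the per-step minibatch description for K steps (consumes the
## minibatch RNG stream). Returns an integer matrix: K rows, n columns for
## explicit indices, or a K x 1 matrix of subset ids for the table scheme.
draw_minibatch_ids <- function(scheme, K) {
  switch(scheme$type,
    none = NULL,
    subset_table = matrix(
      ceiling(runif(K) * scheme$n_subsets), ncol = 1L),
    replacement = matrix(
      ceiling(runif(K * scheme$n) * scheme$N), nrow = K),
    sample_int = t(vapply(seq_len(K),
                          function(k) sample.int(scheme$N, scheme$n),
                          integer(scheme$n))))
}

minibatch_indices <- function(scheme, ids, k) {
  if (scheme$type == "subset_table") scheme$table[, ids[k, 1L]] else ids[k, ]
}

## ---------------------------------------------------------------------------

default_observables <- function(dim) {
  list(phi1 = function(state) sum(state),
       phi2 = function(state) sum(state^2))
}

#' Run one Euler-Maruyama chain
#'
#' Simulates `config$n_steps` steps from `config$initial_state`, resampling
#' the minibatch at every step when `config$minibatch_size` is set. The
#' chain is deterministic given its RNG streams: noise and minibatch draws
#' live on separate streams derived from `config$seed` (or supplied by
#' [run_ensemble()]), so enabling the stochastic gradient never perturbs the
#' noise sequence.
#'
#' @param target A [target_model()].
#' @param pert A [perturbation_spec()].
#' @param config A [sampler_config()].
#' @param observables Named list of functions of the state; defaults to
#'   `phi1 = sum(theta)` and `phi2 = sum(theta^2)`.
#' @param streams Internal: list with `noise` and `minibatch` RNG states.
#' @param chain_id Internal: provenance label.
#' @return An object of class `em_chain`: list with `states` (thinned,
#'   `theta_0` first), `observable_values` (K x p matrix recorded at
#'   `theta_0 .. theta_{K-1}`), `final_state`, `seed`, `config_digest`,
#'   `kind`, `config`.
#' @export
run_chain <- function(target, pert, config, observables = NULL,
                      streams = NULL, chain_id = 1L) {
  dd <- drift_diffusion(pert$kind, target, pert)
  d <- target$dim
  K <- config$n_steps
  h <- config$step_size
  if (is.null(observables)) observables <- default_observables(d)
  if (is.null(streams)) streams <- chain_streams(config$seed, 1L)[[1L]]
  theta <- config$initial_state
  if (length(theta) != d) stop("initial state has wrong dimension",
                               call. = FALSE)

  scheme <- minibatch_scheme(target$n_data, config$minibatch_size,
                             config$with_replacement)
  use_sg <- scheme$type != "none"

  if (K == 0L) {
    return(structure(list(
      states = matrix(theta, nrow = 1L),
      observable_values = matrix(numeric(0), nrow = 0L,
                                 ncol = length(observables),
                                 dimnames = list(NULL, names(observables))),
      final_state = theta, seed = config$seed,
      config_digest = config_digest(config), kind = pert$kind,
      chain_id = chain_id, config = config), class = "em_chain"))
  }

  noise_draw <- draw_stream(streams$noise, function() rnorm(K * d))
  noise <- matrix(noise_draw$value, nrow = K, ncol = d, byrow = TRUE)
  ids <- if (use_sg)
    draw_stream(streams$minibatch, function() draw_minibatch_ids(scheme, K))$value

  keep <- seq(1L, K + 1L, by = config$thin)
  states <- matrix(NA_real_, nrow = length(keep), ncol = d)
  states[1L, ] <- theta
  kept <- 1L
  obs <- matrix(NA_real_, nrow = K, ncol = length(observables),
                dimnames = list(NULL, names(observables)))

  for (k in seq_len(K)) {
    for (j in seq_along(observables)) obs[k, j] <- observables[[j]](theta)
    grad <- if (use_sg)
      stochastic_gradient(target, theta, scheme$n,
                          indices = minibatch_indices(scheme, ids, k))
    theta <- tryCatch(
      em_step(theta, dd, h, noise[k, ], grad = grad),
      giirr_numerical_error = function(e) {
        e$step <- k
        e$message <- sprintf("%s (step %d, |state| = %.3g)", conditionMessage(e),
                             k, sqrt(sum(e$state^2)))
        stop(e)
      })
    if (kept < length(keep) && keep[kept + 1L] == k + 1L) {
      kept <- kept + 1L
      states[kept, ] <- theta
    }
  }

  structure(list(states = states, observable_values = obs,
                 final_state = theta, seed = config$seed,
                 config_digest = config_digest(config), kind = pert$kind,
                 chain_id = chain_id, config = config),
            class = "em_chain")
}

#' @export
print.em_chain <- function(x, ...) {
  cat(sprintf("<em_chain> kind = %s, %d steps, d = %d\n", x$kind,
              nrow(x$observable_values), ncol(x$states)))
  invisible(x)
}

#' Run an ensemble of independent chains
#'
#' Chain i draws from a pair of RNG streams derived deterministically from
#' `(base_seed, i)`, so ensembles with the same base seed are identical and
#' the first chains of a larger ensemble coincide with a smaller ensemble's
#' chains.
#'
#' @inheritParams run_chain
#' @param n_chains Number of chains (>= 1).
#' @param base_seed Seed from which per-chain streams are derived.
#' @return An object of class `em_ensemble`: list of [run_chain()] results.
#' @export
run_ensemble <- function(target, pert, config, observables = NULL,
                         n_chains = 1L, base_seed = 1L) {
  stopifnot(n_chains >= 1)
  streams <- chain_streams(base_seed, n_chains)
  chains <- lapply(seq_len(n_chains), function(i) {
    run_chain(target, pert, config, observables,
              streams = streams[[i]], chain_id = i)
  })
  structure(list(chains = chains, base_seed = base_seed, kind = pert$kind),
            class = "em_ensemble")
}

#' @export
print.em_ensemble <- function(x, ...) {
  cat(sprintf("<em_ensemble> kind = %s, %d chains\n", x$kind,
              length(x$chains)))
  invisible(x)
}

#' @describeIn run_chain Tidy a chain into a long tibble of states
#'   (`step`, `parameter`, `value`); `step` 0 is the initial state and
#'   reflects thinning.
#' @param x An `em_chain`.
#' @param ... Unused.
#' @export
tidy.em_chain <- function(x, ...) {
  states <- x$states
  thin <- x$config$thin
  steps <- (seq_len(nrow(states)) - 1L) * thin
  colnames(states) <- paste0("theta", seq_len(ncol(states)))
  tibble::as_tibble(states) |>
    dplyr::mutate(step = steps, .before = 1L) |>
    tidyr::pivot_longer(-"step", names_to = "parameter", values_to = "value")
}

#' @describeIn run_ensemble Tidy an ensemble into a long tibble with a
#'   `chain` column.
#' @param x An `em_ensemble`.
#' @param ... Unused.
#' @export
tidy.em_ensemble <- function(x, ...) {
  purrr::map_dfr(seq_along(x$chains), function(i)
    dplyr::mutate(tidy(x$chains[[i]]), chain = i, .before = 1L))
}
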