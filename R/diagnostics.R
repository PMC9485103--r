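## Estimator-quality diagnostics: running averages, ensemble bias/variance/
## MSE against a reference expectation, batch-means asymptotic variance,
## kernelized Stein discrepancy (inverse multiquadric base kernel), and the
## exact stationary law of the discretized linear-Gaussian recursion.

#' Running average of an observable series
#'
#' Element K of the result is the mean of the first K values, i.e. the
#' long-term-average estimator as a function of chain length.
#'
#' @param values Non-empty numeric vector.
#' @return Numeric vector of prefix means.
#' @export
running_average <- function(values) {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  cumsum(values) / seq_along(values)
}

#' Ensemble bias, variance and MSE curves
#'
#' Given the running-average curves of one observable over M independent
#' chains and a reference expectation, computes the across-chain bias,
#' (population) variance and mean-squared error at every chain length, with
#' `mse = bias^2 + variance` by construction.
#'
#' @param observable_curves M x K matrix of running averages (rows are
#'   chains), or a list of equal-length numeric vectors.
#' @param reference Scalar reference value of the expectation (analytic, or
#'   from a long reference run).
#' @return A tibble with columns `K`, `bias`, `variance`, `mse`.
#' @export
ensemble_bias_var_mse <- function(observable_curves, reference) {
  if (is.list(observable_curves)) {
    lens <- lengths(observable_curves)
    if (length(unique(lens)) != 1L)
      stop("all chains must have the same curve length", call. = FALSE)
    observable_curves <- do.call(rbind, observable_curves)
  }
  m <- nrow(observable_curves)
  if (m < 2L) stop("need at least 2 chains for a variance", call. = FALSE)
  mean_curve <- colMeans(observable_curves)
  bias <- mean_curve - reference
  variance <- colMeans(observable_curves^2) - mean_curve^2
  tibble::tibble(K = seq_len(ncol(observable_curves)), bias = bias,
                 variance = variance, mse = bias^2 + variance)
}

#' Batch-means asymptotic variance
#'
#' Discards `burn_in_steps` values, splits the remaining K' values into
#' `n_batches` contiguous batches of length `L = floor(K'/n_batches)`
#' (dropping the tail remainder), and returns `L * h` times the unbiased
#' sample variance of the batch means -- the batch-means estimate of the
#' asymptotic variance `lim t Var(t^-1 int_0^t phi dt)` in time units.
#'
#' @param series Observable values recorded at every step.
#' @param h Step size (converts batch length to time).
#' @param burn_in_steps Leading values to discard.
#' @param n_batches Number of batches (default 20).
#' @return Scalar asymptotic-variance estimate.
#' @export
batch_means_avar <- function(series, h, burn_in_steps = 0L, n_batches = 20L) {
  series <- as.numeric(series)
  if (burn_in_steps > 0L) series <- series[-seq_len(burn_in_steps)]
  Kp <- length(series)
  if (Kp < 2L * n_batches)
    stop(sprintf("need at least %d post-burn-in values (got %d)",
                 2L * n_batches, Kp), call. = FALSE)
  L <- Kp %/% n_batches
  means <- colMeans(matrix(series[seq_len(L * n_batches)], nrow = L))
  L * h * stats::var(means)
}

#' Kernelized Stein discrepancy configuration
#'
#' The base kernel is the inverse multiquadric
#' `r(x, y) = (c^2 + ||x - y||^2)^q` with exponent `q` in (-1, 0).
#'
#' @param kernel_scale Scale c > 0 (default 1).
#' @param kernel_exponent Exponent `q` (default -1/2).
#' @param block_size Number of samples per block in the pairwise pass
#'   (memory control; default 1024).
#' @param evaluation_points Increasing integer vector of chain lengths at
#'   which the running KSD curve is evaluated (default: log-spaced).
#' @param normalized Divide each `w_j` by K (default `TRUE`), so the KSD of
#'   i.i.d. samples decays like `K^(-1/2)`; `FALSE` gives the raw pairwise
#'   root-sum.
#' @return An object of class `ksd_config`.
#' @export
ksd_config <- function(kernel_scale = 1, kernel_exponent = -0.5,
                       block_size = 1024L, evaluation_points = NULL,
                       normalized = TRUE) {
  if (!is.numeric(kernel_scale) || kernel_scale <= 0)
    stop("`kernel_scale` must be positive", call. = FALSE)
  if (kernel_exponent <= -1 || kernel_exponent >= 0)
    stop("`kernel_exponent` must lie in (-1, 0)", call. = FALSE)
  structure(list(kernel_scale = kernel_scale,
                 kernel_exponent = kernel_exponent,
                 block_size = as.integer(block_size),
                 evaluation_points = evaluation_points,
                 normalized = isTRUE(normalized)),
            class = "ksd_config")
}

## Blockwise sums of the Stein kernel r0^j over all pairs (rows of Xa) x
## (rows of Xb). Sa, Sb are the score matrices (rows = grad log pi at each
## sample). Returns a d-vector of block sums.
stein_block_sums <- function(Xa, Xb, Sa, Sb, cfg) {
  d <- ncol(Xa)
  q <- cfg$kernel_exponent
  c2 <- cfg$kernel_scale^2
  U <- vector("list", d)
  D2 <- 0
  for (j in seq_len(d)) {
    U[[j]] <- outer(Xa[, j], Xb[, j], "-")
    D2 <- D2 + U[[j]]^2
  }
  s <- c2 + D2
  r <- s^q
  sp1 <- s^(q - 1)
  sp2 <- s^(q - 2)
  out <- numeric(d)
  for (j in seq_len(d)) {
    u <- U[[j]]
    ## r0^j = bj(x) bj(y) r - 2q bj(x) s^(q-1) u + 2q bj(y) s^(q-1) u
    ##        - 4q(q-1) s^(q-2) u^2 - 2q s^(q-1)
    block <- tcrossprod(Sa[, j], Sb[, j]) * r +
      (-2 * q) * (Sa[, j] * (sp1 * u)) +
      (2 * q) * t(t(sp1 * u) * Sb[, j]) +
      (-4 * q * (q - 1)) * sp2 * u^2 +
      (-2 * q) * sp1
    out[j] <- sum(block)
  }
  out
}

#' Stein kernel of the inverse multiquadric base kernel
#'
#' Component j is `r0^j(x, y) = b_j(x) b_j(y) r + b_j(x) d_{y_j} r +
#' b_j(y) d_{x_j} r + d_{x_j} d_{y_j} r`, with `b = grad log pi` and `r` the
#' inverse multiquadric kernel; all derivatives are analytic. Its expectation
#' under pi vanishes (Stein's identity), which is what makes the pairwise
#' sums a discrepancy.
#'
#' @param x,y States of equal dimension.
#' @param grad_log_density Score function (d-vector -> d-vector).
#' @param config A [ksd_config()].
#' @return d-vector of Stein-kernel components.
#' @export
stein_kernel <- function(x, y, grad_log_density, config = ksd_config()) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal dimension",
                                   call. = FALSE)
  Xa <- matrix(x, nrow = 1L)
  Xb <- matrix(y, nrow = 1L)
  Sa <- matrix(grad_log_density(x), nrow = 1L)
  Sb <- matrix(grad_log_density(y), nrow = 1L)
  stein_block_sums(Xa, Xb, Sa, Sb, config)
}

#' Kernelized Stein discrepancy of a sample
#'
#' Computes `S = ||w||_2` with `w_j = (1/K) sqrt(sum_{k,k'} r0^j(x_k,
#' x_k'))` over all ordered sample pairs (the `1/K` normalization makes the
#' statistic an estimate of the kernel Stein discrepancy of the empirical
#' measure, decaying like `K^(-1/2)` for exact samples; set
#' `normalized = FALSE` in the config for the raw root-sum). Pairwise sums
#' are evaluated blockwise with bounded memory, and a running curve at the
#' configured evaluation points is obtained from cumulative pair sums in a
#' single O(K^2) pass.
#'
#' @param samples K x d matrix of states (a vector is treated as K x 1).
#' @param grad_log_density Score function: d-vector -> d-vector, or a
#'   function mapping a K x d matrix to a K x d matrix of scores.
#' @param config A [ksd_config()].
#' @return An object of class `ksd_result`: list with `ksd` (the value at
#'   the full K), `curve` (tibble `K`, `value`), and `config`.
#' @export
ksd <- function(samples, grad_log_density, config = ksd_config()) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  K <- nrow(samples)
  d <- ncol(samples)
  if (K < 1L) stop("need at least one sample", call. = FALSE)

  scores <- grad_log_density(samples)
  if (is.null(dim(scores)) || !all(dim(scores) == dim(samples)))
    scores <- t(apply(samples, 1L, grad_log_density))
  if (d == 1L) scores <- matrix(as.vector(scores), ncol = 1L)
  if (!all(is.finite(scores)))
    stop("non-finite score encountered in ksd()", call. = FALSE)

  pts <- config$evaluation_points
  if (is.null(pts)) {
    pts <- unique(round(10^seq(log10(min(10, K)), log10(K), length.out = 20L)))
    pts <- pts[pts >= 1L & pts <= K]
  }
  pts <- sort(unique(as.integer(c(pts, K))))
  pts <- pts[pts >= 1L & pts <= K]

  bs <- config$block_size
  tot <- numeric(d)    # sum over all pairs among the first `prev` samples
  prev <- 0L
  values <- numeric(length(pts))
  for (e in seq_along(pts)) {
    pt <- pts[e]
    if (pt > prev) {
      new_idx <- (prev + 1L):pt
      ## cross terms old x new (r0 is symmetric, count both orders)
      if (prev > 0L) {
        for (a0 in seq(1L, prev, by = bs)) {
          a1 <- min(a0 + bs - 1L, prev)
          for (b0 in seq(prev + 1L, pt, by = bs)) {
            b1 <- min(b0 + bs - 1L, pt)
            tot <- tot + 2 * stein_block_sums(
              samples[a0:a1, , drop = FALSE], samples[b0:b1, , drop = FALSE],
              scores[a0:a1, , drop = FALSE], scores[b0:b1, , drop = FALSE],
              config)
          }
        }
      }
      ## new x new block (includes the diagonal pairs)
      for (a0 in seq(prev + 1L, pt, by = bs)) {
        a1 <- min(a0 + bs - 1L, pt)
        for (b0 in seq(prev + 1L, pt, by = bs)) {
          b1 <- min(b0 + bs - 1L, pt)
          tot <- tot + stein_block_sums(
            samples[a0:a1, , drop = FALSE], samples[b0:b1, , drop = FALSE],
            scores[a0:a1, , drop = FALSE], scores[b0:b1, , drop = FALSE],
            config)
        }
      }
      prev <- pt
    }
    if (any(!is.finite(tot)))
      stop(sprintf("non-finite Stein-kernel sum at K = %d", pt), call. = FALSE)
    w2 <- pmax(tot, 0)
    values[e] <- if (config$normalized)
      sqrt(sum(w2)) / pt else sqrt(sum(w2))
  }

  structure(list(ksd = values[length(values)],
                 curve = tibble::tibble(K = pts, value = values),
                 config = config),
            class = "ksd_result")
}

#' @export
print.ksd_result <- function(x, ...) {
  cat(sprintf("<ksd_result> KSD = %.4g at K = %d\n", x$ksd,
              max(x$curve$K)))
  invisible(x)
}

#' @describeIn ksd Tidy the running KSD curve.
#' @param x A `ksd_result`.
#' @param ... Unused.
#' @export
tidy.ksd_result <- function(x, ...) x$curve

#' Least-squares slope of a log-log KSD curve
#'
#' @param curve Tibble with columns `K` and `value` (e.g. from [ksd()]), or
#'   a `ksd_result`.
#' @param min_K Discard points below this chain length before fitting.
#' @return Scalar slope of `log10(value)` against `log10(K)`.
#' @export
ksd_slope <- function(curve, min_K = 1L) {
  if (inherits(curve, "ksd_result")) curve <- curve$curve
  curve <- curve[curve$K >= min_K & curve$value > 0, ]
  if (nrow(curve) < 2L) stop("need at least two curve points", call. = FALSE)
  unname(coef(lm(log10(value) ~ log10(K), data = curve))[2L])
}

#' Exact stationary law of the discretized linear-Gaussian recursion
#'
#' For the recurrence `theta' = (I - h A) theta + h offset + sqrt(h) xi`,
#' `xi ~ N(0, Q)`, the stationary mean solves `A m = offset` and the
#' stationary covariance solves the discrete Lyapunov equation
#' `Sigma = F Sigma F' + h Q` with `F = I - h A`. This is the exact law the
#' Euler-Maruyama chain of any constant-coefficient sampler targets, making
#' it an oracle for the discretization bias.
#'
#' @param drift_matrix A (d x d); the chain drift is `-A theta + offset`.
#' @param drift_offset Offset vector (default zero).
#' @param noise_covariance Q (d x d; default `2 * beta * I` with beta = 1/2,
#'   i.e. the identity).
#' @param h Step size.
#' @return List with `mean` and `covariance`.
#' @export
em_stationary_law <- function(drift_matrix, drift_offset = NULL,
                              noise_covariance = NULL, h) {
  A <- as.matrix(drift_matrix)
  d <- nrow(A)
  if (is.null(drift_offset)) drift_offset <- numeric(d)
  if (is.null(noise_covariance)) noise_covariance <- diag(d)
  F_ <- diag(d) - h * A
  if (max(Mod(eigen(F_, only.values = TRUE)$values)) >= 1)
    stop("(I - h A) is not a contraction; use a smaller step size h",
         call. = FALSE)
  m <- drop(solve(A, drift_offset))
  vec_sigma <- solve(diag(d * d) - kronecker(F_, F_),
                     h * as.vector(noise_covariance))
  sigma <- matrix(vec_sigma, d, d)
  list(mean = m, covariance = (sigma + t(sigma)) / 2)
}
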