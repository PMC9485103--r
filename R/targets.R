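## Target posteriors.
##
## A target bundles everything a Langevin sampler needs: the unnormalized
## log-density, its gradient (split into prior and per-datum likelihood terms
## for minibatching), and -- when a Riemannian metric is used -- the matrix
## B(theta), a factor sqrt(B) with sqrt(B) sqrt(B)' = B, the divergence
## vector (div B)_i = sum_j dB_ij/dtheta_j, and the full derivative tensor
## dB_ij/dtheta_k needed by the geometry-informed irreversible correction.

#' Construct a target model
#'
#' Low-level constructor for the posterior contract used throughout the
#' package. The four shipped posteriors ([gaussian_posterior()],
#' [normal_params_model()], [logistic_model()], [ica_model()]) are built on
#' top of this.
#'
#' @param dim State dimension d.
#' @param log_density Function: d-vector -> scalar, unnormalized log pi.
#' @param grad_log_density Function: d-vector -> d-vector.
#' @param prior_grad Function: d-vector -> d-vector, gradient of the log-prior
#'   (zero function if `NULL`).
#' @param datum_grad Function: (d-vector, index) -> d-vector, gradient of the
#'   log-likelihood term of one data point.
#' @param minibatch_grad Optional function `(state, indices)` returning the
#'   stochastic-gradient estimate `prior_grad + (N/n) * sum(datum_grad)`; a
#'   generic loop over `datum_grad` is used when absent.
#' @param n_data Number of data points N (0 when no factorized likelihood).
#' @param metric,metric_sqrt,metric_div,metric_deriv Functions of the state
#'   returning B (d x d), sqrt(B) (d x d), div B (d) and the d x d x d array
#'   of entries `dB[i,j]/dtheta[k]`. All `NULL` for a metric-free target.
#' @param constant_metric Logical; `TRUE` when B does not depend on the state
#'   (its divergence and derivative then vanish identically).
#' @param domain Optional function: d-vector -> logical, admissibility check.
#' @param name Display name.
#' @return An object of class `target_model`.
#' @export
target_model <- function(dim, log_density, grad_log_density,
                         prior_grad = NULL, datum_grad = NULL,
                         minibatch_grad = NULL, n_data = 0L,
                         metric = NULL, metric_sqrt = NULL,
                         metric_div = NULL, metric_deriv = NULL,
                         constant_metric = FALSE, domain = NULL,
                         name = "target") {
  stopifnot(is.numeric(dim), dim >= 1, is.function(log_density),
            is.function(grad_log_density))
  if (is.null(prior_grad)) prior_grad <- function(state) numeric(dim)
  obj <- structure(
    list(dim = as.integer(dim), log_density = log_density,
         grad_log_density = grad_log_density, prior_grad = prior_grad,
         datum_grad = datum_grad, minibatch_grad = minibatch_grad,
         n_data = as.integer(n_data), metric = metric,
         metric_sqrt = metric_sqrt, metric_div = metric_div,
         metric_deriv = metric_deriv, constant_metric = constant_metric,
         domain = domain, name = name),
    class = "target_model")
  obj
}

#' @export
print.target_model <- function(x, ...) {
  cat(sprintf("<target_model> %s: d = %d, N = %d, metric: %s\n",
              x$name, x$dim, x$n_data,
              if (is.null(x$metric)) "none" else
                if (x$constant_metric) "constant" else "state-dependent"))
  invisible(x)
}

has_metric <- function(target) !is.null(target$metric)

check_spd <- function(m, label) {
  if (!is.matrix(m) || nrow(m) != ncol(m) ||
      max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    stop(sprintf("`%s` must be a symmetric matrix", label), call. = FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop(sprintf("`%s` is not positive definite (min eigenvalue %.3g)",
                 label, min(ev)), call. = FALSE)
  invisible(TRUE)
}

## Symmetric PSD square root via eigendecomposition (unique symmetric root).
sym_sqrt <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  e$vectors %*% (sqrt(vals) * t(e$vectors))
}

## ---------------------------------------------------------------------------
## Linear-Gaussian posterior

#' Conjugate linear-Gaussian posterior
#'
#' Posterior for the mean `theta` of i.i.d. Gaussian observations
#' `X_i ~ N(theta, noise_precision^-1)` under a zero-mean Gaussian prior with
#' precision `prior_precision`. The posterior is Gaussian with precision
#' `Gamma_p = prior_precision + N * noise_precision` and mean solving
#' `Gamma_p mu_p = noise_precision %*% colSums(X)`. Also assembles the
#' Euler-Maruyama drift pair `A = Gamma_p / 2`, `D = noise_precision %*%
#' colSums(X) / 2` of the discretized Langevin recursion at temperature 1/2.
#'
#' The derived target carries the constant metric `B = Gamma_p^-1`, the
#' choice used by the reversible perturbation in the linear-Gaussian study.
#'
#' @param prior_precision d x d SPD prior precision.
#' @param noise_precision d x d SPD observation precision.
#' @param data N x d matrix of observations (a vector is treated as N x 1).
#' @return An object of class `linear_gaussian` with fields
#'   `posterior_mean`, `posterior_precision`, `drift_matrix`, `drift_offset`,
#'   the inputs, and `target` (a [target_model()]).
#' @export
gaussian_posterior <- function(prior_precision, noise_precision, data) {
  if (is.vector(data)) data <- matrix(data, ncol = 1L)
  prior_precision <- as.matrix(prior_precision)
  noise_precision <- as.matrix(noise_precision)
  d <- ncol(data)
  N <- nrow(data)
  if (N < 1) stop("need at least one observation", call. = FALSE)
  check_spd(prior_precision, "prior_precision")
  check_spd(noise_precision, "noise_precision")
  stopifnot(nrow(prior_precision) == d, nrow(noise_precision) == d)

  data_sum <- colSums(data)
  gamma_p <- prior_precision + N * noise_precision
  mu_p <- drop(solve(gamma_p, noise_precision %*% data_sum))
  B <- solve(gamma_p)
  B_sqrt <- sym_sqrt(B)
  zero_vec <- numeric(d)
  zero_tensor <- array(0, dim = c(d, d, d))

  tgt <- target_model(
    dim = d,
    log_density = function(state)
      -0.5 * drop(crossprod(state - mu_p, gamma_p %*% (state - mu_p))),
    grad_log_density = function(state) drop(-gamma_p %*% (state - mu_p)),
    prior_grad = function(state) drop(-prior_precision %*% state),
    datum_grad = function(state, i) drop(noise_precision %*% (data[i, ] - state)),
    minibatch_grad = function(state, indices) {
      n <- length(indices)
      sub_sum <- colSums(data[indices, , drop = FALSE])
      drop(-prior_precision %*% state) +
        (N / n) * drop(noise_precision %*% (sub_sum - n * state))
    },
    n_data = N,
    metric = function(state) B,
    metric_sqrt = function(state) B_sqrt,
    metric_div = function(state) zero_vec,
    metric_deriv = function(state) zero_tensor,
    constant_metric = TRUE,
    name = "linear_gaussian")

  structure(
    list(prior_precision = prior_precision, noise_precision = noise_precision,
         data = data, n_data = N, posterior_mean = mu_p,
         posterior_precision = gamma_p,
         drift_matrix = 0.5 * gamma_p,
         drift_offset = 0.5 * drop(noise_precision %*% data_sum),
         target = tgt),
    class = "linear_gaussian")
}

#' @export
print.linear_gaussian <- function(x, ...) {
  cat(sprintf("<linear_gaussian> d = %d, N = %d\n", length(x$posterior_mean),
              x$n_data))
  cat("posterior mean:", signif(x$posterior_mean, 4), "\n")
  invisible(x)
}

## ---------------------------------------------------------------------------
## Mean and standard deviation of a normal distribution

#' Posterior over the mean and standard deviation of a normal sample
#'
#' Flat (improper) prior on `(mu, sigma)`; the state is `theta = (mu, sigma)`
#' with `sigma > 0`. The log-posterior is `-N log sigma - sum((X - mu)^2) /
#' (2 sigma^2)` and the gradient is `(m1/sigma^2, -N/sigma + m2/sigma^3)`
#' with `m1 = sum(X - mu)`, `m2 = sum((X - mu)^2)`. The metric is the inverse
#' expected Fisher information, `B = (sigma^2/N) diag(1, 1/2)`, with
#' `sqrt(B) = (sigma/sqrt(N)) diag(1, 1/sqrt(2))` and
#' `div B = (0, sigma/N)`.
#'
#' Minibatch gradients replace the data sums `m1`, `m2` by `(N/n)`-scaled
#' subsample sums. Evaluating any quantity at `sigma <= 0` raises a domain
#' error; there is no silent reflection.
#'
#' @param data Numeric vector of observations.
#' @return A [target_model()] over `(mu, sigma)`.
#' @export
normal_params_model <- function(data) {
  data <- as.numeric(data)
  N <- length(data)
  if (N < 1) stop("`data` must be non-empty", call. = FALSE)
  S1 <- sum(data)
  S2 <- sum(data^2)

  check_sigma <- function(state) {
    if (state[2L] <= 0)
      stop_numerical("sigma <= 0 in the normal-parameters target",
                     state = state)
  }
  grad_from_sums <- function(state, s1, s2, n_eff) {
    mu <- state[1L]; sigma <- state[2L]
    m1 <- (N / n_eff) * (s1 - n_eff * mu)
    m2 <- (N / n_eff) * (s2 - 2 * mu * s1 + n_eff * mu^2)
    c(m1 / sigma^2, -N / sigma + m2 / sigma^3)
  }

  target_model(
    dim = 2L,
    log_density = function(state) {
      check_sigma(state)
      mu <- state[1L]; sigma <- state[2L]
      m2 <- S2 - 2 * mu * S1 + N * mu^2
      -N * log(sigma) - m2 / (2 * sigma^2)
    },
    grad_log_density = function(state) {
      check_sigma(state)
      grad_from_sums(state, S1, S2, N)
    },
    prior_grad = function(state) c(0, 0),
    datum_grad = function(state, i) {
      check_sigma(state)
      mu <- state[1L]; sigma <- state[2L]
      r <- data[i] - mu
      c(r / sigma^2, -1 / sigma + r^2 / sigma^3)
    },
    minibatch_grad = function(state, indices) {
      check_sigma(state)
      x <- data[indices]
      grad_from_sums(state, sum(x), sum(x^2), length(indices))
    },
    n_data = N,
    metric = function(state) {
      check_sigma(state)
      (state[2L]^2 / N) * diag(c(1, 0.5))
    },
    metric_sqrt = function(state) {
      check_sigma(state)
      (state[2L] / sqrt(N)) * diag(c(1, 1 / sqrt(2)))
    },
    metric_div = function(state) {
      check_sigma(state)
      c(0, state[2L] / N)
    },
    metric_deriv = function(state) {
      check_sigma(state)
      d <- array(0, dim = c(2L, 2L, 2L))
      d[, , 2L] <- (2 * state[2L] / N) * diag(c(1, 0.5))
      d
    },
    domain = function(state) state[2L] > 0,
    name = "normal_params")
}

## ---------------------------------------------------------------------------
## Bayesian logistic regression

#' Bayesian logistic-regression posterior
#'
#' Weights `w` for binary labels `t_i` with covariate rows `x_i`, logistic
#' link `phi(y) = 1/(1 + exp(-y))` and Gaussian prior `N(0, alpha^-1 I)`. The
#' gradient of the log-posterior is `-alpha w + sum_i (t_i - phi(x_i' w)) x_i`.
#'
#' The metric is `B(w) = I + G(w)^-1` with `G(w) = alpha^-1 I + X' Lambda(w)
#' X` and `Lambda_ii = phi_i (1 - phi_i)` (expected Fisher information plus
#' the prior Hessian, shifted so that `B - I` is positive definite). Its
#' derivative tensor is assembled analytically from
#' `dB/dw_k = -G^-1 (X' dLambda_k X) G^-1`,
#' `(dLambda_k)_ii = phi_i (1 - phi_i) (1 - 2 phi_i) x_ik`.
#'
#' @param features N x d numeric matrix (rows are observations).
#' @param labels Length-N vector with entries in `{0, 1}`.
#' @param alpha Prior precision, `> 0` (default 1; the reference studies do
#'   not pin this value down).
#' @return A [target_model()] over the weight vector.
#' @export
logistic_model <- function(features, labels, alpha = 1) {
  X <- as.matrix(features)
  labels <- as.numeric(labels)
  N <- nrow(X); d <- ncol(X)
  if (!all(labels %in% c(0, 1)))
    stop("`labels` must all be 0 or 1", call. = FALSE)
  if (length(labels) != N)
    stop("`labels` length must match nrow(features)", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0)
    stop("`alpha` must be positive", call. = FALSE)

  lin <- function(w) drop(X %*% w)
  G_of <- function(w) {
    p <- stats::plogis(lin(w))
    lam <- p * (1 - p)
    diag(d) / alpha + crossprod(X, X * lam)
  }

  target_model(
    dim = d,
    log_density = function(w) {
      y <- lin(w)
      sum(labels * y - log1p(exp(y))) - 0.5 * alpha * sum(w^2)
    },
    grad_log_density = function(w) {
      p <- stats::plogis(lin(w))
      drop(crossprod(X, labels - p)) - alpha * w
    },
    prior_grad = function(w) -alpha * w,
    datum_grad = function(w, i) {
      p <- stats::plogis(sum(X[i, ] * w))
      (labels[i] - p) * X[i, ]
    },
    minibatch_grad = function(w, indices) {
      n <- length(indices)
      Xs <- X[indices, , drop = FALSE]
      p <- stats::plogis(drop(Xs %*% w))
      -alpha * w + (N / n) * drop(crossprod(Xs, labels[indices] - p))
    },
    n_data = N,
    metric = function(w) diag(d) + solve(G_of(w)),
    metric_sqrt = function(w) sym_sqrt(diag(d) + solve(G_of(w))),
    metric_div = function(w) {
      dv <- logistic_metric_deriv(X, w, alpha)
      vapply(seq_len(d), function(i) sum(diag(dv[i, , ])), numeric(1))
    },
    metric_deriv = function(w) logistic_metric_deriv(X, w, alpha),
    name = "logistic")
}

## dB_ij/dw_k for B = I + G^-1: dB/dw_k = -G^-1 (X' dLambda_k X) G^-1.
logistic_metric_deriv <- function(X, w, alpha) {
  d <- ncol(X)
  p <- stats::plogis(drop(X %*% w))
  lam <- p * (1 - p)
  lam_prime <- lam * (1 - 2 * p)
  G <- diag(d) / alpha + crossprod(X, X * lam)
  Ginv <- solve(G)
  out <- array(0, dim = c(d, d, d))
  for (k in seq_len(d)) {
    dG <- crossprod(X, X * (lam_prime * X[, k]))
    out[, , k] <- -Ginv %*% dG %*% Ginv
  }
  out
}

#' Read a plain-text logistic-regression table
#'
#' Whitespace- or comma-separated numeric table, one row per observation,
#' last column the `{0, 1}` label and all other columns treated as features
#' (the layout of the "german numeric" table).
#'
#' @param path File path.
#' @return A list with `features` (N x d matrix) and `labels` (length-N).
#' @export
read_logistic_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, sep = sep, header = FALSE)
  tab <- as.matrix(tab)
  if (!is.numeric(tab)) stop("table must be numeric", call. = FALSE)
  labels <- tab[, ncol(tab)]
  if (!all(labels %in% c(0, 1)))
    stop("last column must contain only 0/1 labels", call. = FALSE)
  list(features = tab[, -ncol(tab), drop = FALSE], labels = as.numeric(labels))
}

## ---------------------------------------------------------------------------
## Bayesian independent component analysis

#' Bayesian ICA posterior over the de-mixing matrix
#'
#' Infers a de-mixing matrix `W` (m x m) for observed mixed signals
#' `X = M s`, under the heavy-tailed source likelihood `p(y) = (1/4)
#' sech^2(y/2)` (the standard logistic density) applied to `y = W x`, a
#' Gaussian prior with precision `lambda` on each entry of `W`, and the
#' `|det W|` change-of-variables factor. The state is `vec(W)` stacked
#' column-major, `d = m^2`.
#'
#' The matrix gradient is `f(W) = N (W')^-1 - sum_n tanh(y_n/2) x_n' -
#' lambda W`; the minibatch estimate scales only the data sum by `N/n`
#' (the `N (W')^-1` and prior terms are data-index free). The metric is the
#' natural-gradient-style `B(W) = (I + W'W) (x) I_m`, with
#' `sqrt(B) = (I + W'W)^(1/2) (x) I_m`, `div B = (m+1) vec(W)`, and an
#' analytic derivative tensor.
#'
#' @param mixed_signals m x N matrix whose columns are observations (an
#'   m x 0 matrix is allowed: the posterior is then just the prior).
#' @param lambda Prior precision on the entries of `W`, `>= 0` (default 1).
#' @return A [target_model()] over `vec(W)`.
#' @export
ica_model <- function(mixed_signals, lambda = 1) {
  X <- as.matrix(mixed_signals)
  m <- nrow(X); N <- ncol(X)
  if (m < 2) stop("need at least 2 channels", call. = FALSE)
  if (!is.numeric(lambda) || lambda < 0)
    stop("`lambda` must be >= 0", call. = FALSE)
  d <- m * m

  as_W <- function(state) matrix(state, m, m)
  inv_Wt <- function(W, state) {
    out <- tryCatch(solve(t(W)), error = function(e) NULL)
    if (is.null(out) || !all(is.finite(out)))
      stop_numerical("singular de-mixing matrix W in the ICA target",
                     state = state)
    out
  }
  data_term <- function(W, idx) {
    ## -sum_{n in idx} tanh(y_n / 2) x_n'
    if (length(idx) == 0L) return(matrix(0, m, m))
    Xs <- X[, idx, drop = FALSE]
    Y <- W %*% Xs
    -tanh(Y / 2) %*% t(Xs)
  }

  target_model(
    dim = d,
    log_density = function(state) {
      W <- as_W(state)
      det_W <- det(W)
      if (!is.finite(det_W) || det_W == 0)
        stop_numerical("singular de-mixing matrix W in the ICA target",
                       state = state)
      ll <- N * log(abs(det_W)) - 0.5 * lambda * sum(W^2)
      if (N > 0) {
        Y <- W %*% X
        ll <- ll + sum(-2 * log(2 * cosh(Y / 2)))
      }
      ll
    },
    grad_log_density = function(state) {
      W <- as_W(state)
      f <- N * inv_Wt(W, state) + data_term(W, seq_len(N)) - lambda * W
      as.vector(f)
    },
    prior_grad = function(state) as.vector(-lambda * as_W(state)),
    datum_grad = function(state, i) {
      W <- as_W(state)
      as.vector(inv_Wt(W, state) + data_term(W, i))
    },
    minibatch_grad = function(state, indices) {
      W <- as_W(state)
      n <- length(indices)
      f <- N * inv_Wt(W, state) + (N / n) * data_term(W, indices) - lambda * W
      as.vector(f)
    },
    n_data = N,
    metric = function(state) {
      W <- as_W(state)
      kronecker(diag(m) + crossprod(W), diag(m))
    },
    metric_sqrt = function(state) {
      W <- as_W(state)
      kronecker(sym_sqrt(diag(m) + crossprod(W)), diag(m))
    },
    metric_div = function(state) (m + 1) * state,
    metric_deriv = function(state) ica_metric_deriv(as_W(state)),
    domain = function(state) abs(det(as_W(state))) > .Machine$double.eps,
    name = "ica")
}

## dB_pq/dtheta_r for B = (I + W'W) (x) I_m, theta = vec(W) column-major:
## with p = (a-1)m + i, q = (b-1)m + j, r = (c-1)m + l,
## dB_pq/dW_lc = delta_ij (delta_ac W_lb + delta_bc W_la).
ica_metric_deriv <- function(W) {
  m <- nrow(W)
  d <- m * m
  out <- array(0, dim = c(d, d, d))
  for (a in seq_len(m)) for (b in seq_len(m)) for (c in seq_len(m)) {
    ## dS_ab/dW_lc = delta_ac W_lb + delta_bc W_la, entering along the
    ## diagonal (i = j) of the (a, b) m x m block:
    for (l in seq_len(m)) {
      val <- (if (a == c) W[l, b] else 0) + (if (b == c) W[l, a] else 0)
      if (val != 0) {
        rows <- (a - 1L) * m + seq_len(m)
        cols <- (b - 1L) * m + seq_len(m)
        r <- (c - 1L) * m + l
        out[cbind(rows, cols, r)] <- val
      }
    }
  }
  out
}

## Condition class for numerical-domain failures (carries the state; the
## integrator adds the step index).
stop_numerical <- function(message, state = NULL, step = NULL) {
  stop(structure(
    class = c("giirr_numerical_error", "error", "condition"),
    list(message = message, call = sys.call(-1), state = state, step = step)))
}
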