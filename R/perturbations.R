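## Perturbations of Langevin dynamics.
##
## Five SDE systems share the invariant density pi: plain Langevin (LD), the
## reversible Riemannian-metric perturbation (RM), the constant-skew
## irreversible perturbation (Irr), both together (RMIrr), and the
## geometry-informed irreversible perturbation (GiIrr) whose state-dependent
## skew matrix is C(theta) = (J B(theta) + B(theta) J) / 2 with divergence
## correction div C.

KINDS <- c("LD", "RM", "Irr", "RMIrr", "GiIrr")

match_kind <- function(kind) {
  i <- match(tolower(kind), tolower(KINDS))
  if (is.na(i))
    stop(sprintf("unknown sampler kind '%s'; valid kinds: %s", kind,
                 paste(KINDS, collapse = ", ")), call. = FALSE)
  KINDS[i]
}

#' Specify a sampler perturbation
#'
#' @param kind One of `"LD"`, `"RM"`, `"Irr"`, `"RMIrr"`, `"GiIrr"`
#'   (case-insensitive). `LD` and `RM` ignore `skew`; `LD` and `Irr` ignore
#'   the target's metric.
#' @param temperature Temperature `beta > 0` (all reference experiments use
#'   1/2).
#' @param skew Constant skew-symmetric d x d matrix J (see [build_skew()]).
#' @param scale Bookkeeping scalar delta recorded alongside `skew`.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(kind, temperature = 0.5, skew = NULL, scale = 1) {
  kind <- match_kind(kind)
  if (!is.numeric(temperature) || temperature <= 0)
    stop("`temperature` must be positive", call. = FALSE)
  if (!is.null(skew)) {
    skew <- as.matrix(skew)
    if (max(abs(skew + t(skew))) != 0)
      stop("`skew` must satisfy J + t(J) = 0 exactly", call. = FALSE)
  }
  if (kind %in% c("Irr", "RMIrr", "GiIrr") && is.null(skew))
    stop(sprintf("kind '%s' requires a skew matrix", kind), call. = FALSE)
  structure(list(kind = kind, temperature = temperature, skew = skew,
                 scale = scale),
            class = "perturbation_spec")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat(sprintf("<perturbation_spec> kind = %s, beta = %g, J: %s\n",
              x$kind, x$temperature,
              if (is.null(x$skew)) "none" else
                sprintf("%d x %d", nrow(x$skew), ncol(x$skew))))
  invisible(x)
}

#' Build a skew-symmetric generator matrix
#'
#' Three constructions are provided. `"dense_upper_ones"` is the canonical
#' all-ones upper triangle scaled by `delta` (so for d = 3,
#' `delta * [[0,1,1],[-1,0,1],[-1,-1,0]]`). `"random_pm1"` draws a seeded
#' lower-triangular matrix with entries in `{-1, +1}`, subtracts its
#' transpose, zeroes the diagonal and rescales to `norm_target`.
#' `"kronecker"` returns `(I_m (x) C0) + (C0 (x) I_m)` for `d = m^2`, with
#' `C0` following the dense-upper-ones sign pattern, rescaled to
#' `norm_target`.
#'
#' @param pattern One of `"dense_upper_ones"`, `"random_pm1"`, `"kronecker"`.
#' @param d Dimension (`>= 2`; a perfect square for `"kronecker"`).
#' @param delta Scale applied to the dense pattern (default 1).
#' @param seed Seed for `"random_pm1"`.
#' @param norm_target Requested matrix norm after rescaling (`"random_pm1"`
#'   and `"kronecker"`; default 1).
#' @param norm Which matrix norm `norm_target` refers to: `"spectral"`
#'   (default; bounds the stiffness contribution of J) or `"frobenius"`.
#' @return A d x d skew-symmetric matrix.
#' @export
build_skew <- function(pattern = c("dense_upper_ones", "random_pm1", "kronecker"),
                       d, delta = 1, seed = 1L, norm_target = 1,
                       norm = c("spectral", "frobenius")) {
  pattern <- match.arg(pattern)
  norm <- match.arg(norm)
  if (d < 2) stop("`d` must be at least 2", call. = FALSE)
  norm_of <- function(m) if (norm == "spectral") base::norm(m, "2") else
    base::norm(m, "F")
  rescale <- function(m) {
    if (is.null(norm_target)) return(m)
    if (!is.numeric(norm_target) || norm_target <= 0)
      stop("`norm_target` must be positive", call. = FALSE)
    m * (norm_target / norm_of(m))
  }
  upper_ones <- function(d) {
    m <- matrix(0, d, d)
    m[upper.tri(m)] <- 1
    m - t(m)
  }
  switch(pattern,
    dense_upper_ones = delta * upper_ones(d),
    random_pm1 = {
      L <- matrix(0, d, d)
      draw <- draw_stream(make_streams(seed, 1L)[[1L]],
                          function() sample(c(-1, 1), d * (d - 1) / 2,
                                            replace = TRUE))
      L[lower.tri(L)] <- draw$value
      rescale(L - t(L))
    },
    kronecker = {
      m <- sqrt(d)
      if (m != round(m))
        stop("`d` must be a perfect square for the kronecker pattern",
             call. = FALSE)
      m <- as.integer(m)
      C0 <- upper_ones(m)
      rescale(kronecker(diag(m), C0) + kronecker(C0, diag(m)))
    })
}

#' Geometry-informed skew matrix C = (J B + B J) / 2
#'
#' The state-dependent skew-symmetric matrix combining a constant
#' skew-symmetric J with the Riemannian metric B(theta). With `B = I` it
#' reverts to J, i.e. the standard irreversible perturbation.
#'
#' @param B Symmetric d x d matrix (the metric evaluated at a state).
#' @param J Constant skew-symmetric d x d matrix.
#' @return The skew-symmetric d x d matrix `(J %*% B + B %*% J) / 2`.
#' @export
giirr_C <- function(B, J) {
  B <- as.matrix(B); J <- as.matrix(J)
  if (!all(dim(B) == dim(J)))
    stop("`B` and `J` must have the same dimensions", call. = FALSE)
  0.5 * (J %*% B + B %*% J)
}

#' Divergence of the geometry-informed skew matrix
#'
#' Computes `div C` for `C = (J B + B J) / 2` directly from the metric
#' derivative tensor: component i is
#' `(1/2) sum_jk ( J_ik dB_kj/dtheta_j + (dB_ik/dtheta_j) J_kj )`.
#' Exact (no numerical differentiation); the finite-difference cross-check
#' lives in the test suite.
#'
#' @param metric_deriv d x d x d array with entry `[i, j, k] =
#'   dB_ij/dtheta_k`.
#' @param J Constant skew-symmetric d x d matrix.
#' @return The length-d vector `div C`.
#' @export
giirr_divC <- function(metric_deriv, J) {
  d <- nrow(J)
  if (length(dim(metric_deriv)) != 3L || !all(dim(metric_deriv) == d))
    stop("`metric_deriv` must be a d x d x d array matching J", call. = FALSE)
  ## div B of the first index: (div B)_k = sum_j dB_kj/dtheta_j
  div_B <- vapply(seq_len(d),
                  function(k) sum(diag(metric_deriv[k, , ])),
                  numeric(1))
  ## sum_jk dB_ik/dtheta_j J_kj: flatten over (k, j) against vec(J)
  term2 <- matrix(metric_deriv, nrow = d) %*% as.vector(J)
  0.5 * (drop(J %*% div_B) + drop(term2))
}

#' Assemble the drift and diffusion of a perturbed Langevin SDE
#'
#' Returns the drift `b(theta)` and diffusion factor `sigma(theta)` (with
#' `sigma sigma' = 2 beta B`, `B = I` for LD/Irr) of the requested sampler
#' kind:
#'
#' * `LD`:    `b = beta grad`, `sigma = sqrt(2 beta) I`
#' * `RM`:    `b = beta (B grad + div B)`, `sigma = sqrt(2 beta B)`
#' * `Irr`:   `b = (beta I + J) grad`, `sigma = sqrt(2 beta) I`
#' * `RMIrr`: `b = (beta B + J) grad + beta div B`, `sigma = sqrt(2 beta B)`
#' * `GiIrr`: `b = (beta B + C) grad + beta div B + div C`,
#'            `sigma = sqrt(2 beta B)`, with C from [giirr_C()] and `div C`
#'            from [giirr_divC()].
#'
#' The returned drift accepts an optional pre-computed gradient (used by the
#' stochastic-gradient integrator) so the drift operator and the gradient
#' estimate stay decoupled.
#'
#' @param kind Sampler kind (or a [perturbation_spec()] as `pert` with
#'   `kind = pert$kind`).
#' @param target A [target_model()].
#' @param pert A [perturbation_spec()].
#' @return An object of class `drift_diffusion`: list with functions
#'   `drift(state, grad = NULL)` and `diffusion_factor(state)`, and fields
#'   `kind`, `beta`, `constant_diffusion`.
#' @export
drift_diffusion <- function(kind, target, pert) {
  kind <- match_kind(kind)
  beta <- pert$temperature
  d <- target$dim
  J <- pert$skew
  needs_metric <- kind %in% c("RM", "RMIrr", "GiIrr")
  needs_skew <- kind %in% c("Irr", "RMIrr", "GiIrr")
  if (needs_metric && !has_metric(target))
    stop(sprintf("kind '%s' requires a target with a metric", kind),
         call. = FALSE)
  if (needs_skew) {
    if (is.null(J)) stop(sprintf("kind '%s' requires a skew matrix", kind),
                         call. = FALSE)
    if (nrow(J) != d)
      stop("skew matrix dimension does not match the target", call. = FALSE)
  }
  if (kind == "GiIrr" && !target$constant_metric &&
      is.null(target$metric_deriv))
    stop("GiIrr on a state-dependent metric requires `metric_deriv`",
         call. = FALSE)

  sqrt_2b <- sqrt(2 * beta)
  grad_of <- function(state, grad) if (is.null(grad))
    target$grad_log_density(state) else grad

  drift <- switch(kind,
    LD = function(state, grad = NULL) beta * grad_of(state, grad),
    Irr = function(state, grad = NULL) {
      g <- grad_of(state, grad)
      beta * g + drop(J %*% g)
    },
    RM = function(state, grad = NULL) {
      g <- grad_of(state, grad)
      B <- target$metric(state)
      beta * (drop(B %*% g) + target$metric_div(state))
    },
    RMIrr = function(state, grad = NULL) {
      g <- grad_of(state, grad)
      B <- target$metric(state)
      drop((beta * B + J) %*% g) + beta * target$metric_div(state)
    },
    GiIrr = function(state, grad = NULL) {
      g <- grad_of(state, grad)
      B <- target$metric(state)
      C <- giirr_C(B, J)
      div_C <- if (target$constant_metric) 0 else
        giirr_divC(target$metric_deriv(state), J)
      drop((beta * B + C) %*% g) + beta * target$metric_div(state) + div_C
    })

  constant_diffusion <- !needs_metric || target$constant_metric
  diffusion_factor <- if (!needs_metric) {
    sig <- sqrt_2b * diag(d)
    function(state) sig
  } else if (target$constant_metric) {
    sig <- NULL
    function(state) {
      if (is.null(sig)) sig <<- sqrt_2b * target$metric_sqrt(state)
      sig
    }
  } else {
    function(state) sqrt_2b * target$metric_sqrt(state)
  }

  structure(list(drift = drift, diffusion_factor = diffusion_factor,
                 kind = kind, beta = beta, skew = J,
                 constant_diffusion = constant_diffusion, target = target),
            class = "drift_diffusion")
}

#' @export
print.drift_diffusion <- function(x, ...) {
  cat(sprintf("<drift_diffusion> kind = %s, beta = %g, target = %s\n",
              x$kind, x$beta, x$target$name))
  invisible(x)
}
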