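## Compiled fast paths.
##
## The normal-parameters and linear-Gaussian studies need millions of
## Euler-Maruyama steps per chain; those two targets have cheap closed-form
## drifts, so dedicated C++ kernels run them. All randomness (noise,
## minibatch sums) is drawn in R from the chain's streams in exactly the
## order the generic stepper uses, so the kernels reproduce run_chain()
## trajectories; the test suite asserts that equivalence.

## Per-subset sums of the normal-parameters data, matching the generic
## path's sum(data[indices]) element order.
np_subset_tables <- function(data, scheme) {
  if (scheme$type != "subset_table") return(NULL)
  sel <- matrix(data[scheme$table], nrow = scheme$n)
  list(S1 = colSums(sel), S2 = colSums(sel^2))
}

## One chain of the (mu, sigma) target through the C++ kernel.
## Returns phi1/phi2 series (recorded at theta_0 .. theta_{K-1}), the final
## state, and optionally the full state matrix.
run_chain_np <- function(data, kind, config, delta, beta = 0.5,
                         streams = NULL, store_states = FALSE,
                         tables = NULL, scheme = NULL) {
  kind <- match_kind(kind)
  K <- config$n_steps
  N <- length(data)
  if (is.null(streams)) streams <- chain_streams(config$seed, 1L)[[1L]]
  if (is.null(scheme))
    scheme <- minibatch_scheme(N, config$minibatch_size,
                               config$with_replacement)
  noise <- matrix(draw_stream(streams$noise,
                              function() rnorm(K * 2L))$value,
                  nrow = K, ncol = 2L, byrow = TRUE)
  if (scheme$type == "none") {
    S1 <- rep(sum(data), K)
    S2 <- rep(sum(data^2), K)
    nsub <- N
  } else {
    ids <- draw_stream(streams$minibatch,
                       function() draw_minibatch_ids(scheme, K))$value
    nsub <- scheme$n
    if (scheme$type == "subset_table") {
      if (is.null(tables)) tables <- np_subset_tables(data, scheme)
      S1 <- tables$S1[ids[, 1L]]
      S2 <- tables$S2[ids[, 1L]]
    } else {
      sel <- matrix(data[ids], nrow = nrow(ids))
      S1 <- rowSums(sel)
      S2 <- rowSums(sel^2)
    }
  }
  kind_code <- match(kind, KINDS) - 1L
  np_chain_cpp(kind_code, config$initial_state[1L], config$initial_state[2L],
               config$step_size, beta, delta, N, S1, S2, nsub, noise,
               store_states)
}

## One chain of the ICA posterior through the Armadillo kernel. `C0` is the
## m x m generator of the Kronecker skew J = (I (x) C0) + (C0 (x) I),
## already carrying J's rescaling, so the kernel's matrix identities apply.
run_chain_ica <- function(X, kind, config, C0, lambda = 1, beta = 0.5,
                          streams = NULL, store_states = FALSE) {
  kind <- match_kind(kind)
  m <- nrow(X)
  d <- m * m
  K <- config$n_steps
  N <- ncol(X)
  if (is.null(streams)) streams <- chain_streams(config$seed, 1L)[[1L]]
  noise <- matrix(draw_stream(streams$noise,
                              function() rnorm(K * d))$value,
                  nrow = K, ncol = d, byrow = TRUE)
  scheme <- minibatch_scheme(N, config$minibatch_size,
                             config$with_replacement)
  use_sg <- scheme$type != "none"
  ids <- if (use_sg)
    draw_stream(streams$minibatch,
                function() draw_minibatch_ids(scheme, K))$value
  if (use_sg && scheme$type == "subset_table")
    ids <- t(scheme$table[, ids[, 1L], drop = FALSE])
  if (!use_sg) ids <- matrix(0L, 0L, 0L)
  kind_code <- match(kind, KINDS) - 1L
  ica_chain_cpp(kind_code, matrix(config$initial_state, m, m),
                config$step_size, beta, C0, lambda, N, X, noise,
                ids, use_sg, store_states)
}

## Drift matrix M(kind) such that drift = M * grad(log pi), plus the
## diffusion factor, for a constant-metric linear-Gaussian target.
lg_drift_parts <- function(lg, kind, beta, J = NULL) {
  kind <- match_kind(kind)
  d <- length(lg$posterior_mean)
  B <- solve(lg$posterior_precision)
  M <- switch(kind,
    LD = beta * diag(d),
    RM = beta * B,
    Irr = beta * diag(d) + J,
    RMIrr = beta * B + J,
    GiIrr = beta * B + giirr_C(B, J))
  L <- if (kind %in% c("LD", "Irr")) sqrt(2 * beta) * diag(d) else
    sqrt(2 * beta) * sym_sqrt(B)
  list(M = M, L = L, G = -M %*% lg$posterior_precision)
}

## One chain of a linear-Gaussian target through the affine kernel.
run_chain_lg <- function(lg, kind, config, J = NULL, beta = 0.5,
                         streams = NULL, store_states = FALSE) {
  K <- config$n_steps
  d <- length(lg$posterior_mean)
  N <- lg$n_data
  if (is.null(streams)) streams <- chain_streams(config$seed, 1L)[[1L]]
  parts <- lg_drift_parts(lg, kind, beta, J)
  noise <- matrix(draw_stream(streams$noise,
                              function() rnorm(K * d))$value,
                  nrow = K, ncol = d, byrow = TRUE)
  scheme <- minibatch_scheme(N, config$minibatch_size,
                             config$with_replacement)
  if (scheme$type == "none") {
    gamma <- drop(lg$noise_precision %*% colSums(lg$data))
    offsets <- matrix(drop(parts$M %*% gamma), nrow = 1L)
  } else {
    ids <- draw_stream(streams$minibatch,
                       function() draw_minibatch_ids(scheme, K))$value
    scale <- N / scheme$n
    if (scheme$type == "subset_table") {
      ## d x n_subsets table of M Gamma_X (scaled subset sums)
      sub_sums <- apply(scheme$table, 2L,
                        function(idx) colSums(lg$data[idx, , drop = FALSE]))
      if (d == 1L) sub_sums <- matrix(sub_sums, nrow = 1L)
      off_tab <- parts$M %*% (lg$noise_precision %*% sub_sums) * scale
      offsets <- t(off_tab[, ids[, 1L], drop = FALSE])
    } else {
      sums <- t(apply(ids, 1L,
                      function(idx) colSums(lg$data[idx, , drop = FALSE])))
      if (d == 1L) sums <- matrix(as.vector(sums), ncol = 1L)
      offsets <- sums %*% t(lg$noise_precision) %*% t(parts$M) * scale
    }
  }
  affine_chain_cpp(parts$G, offsets, parts$L, config$step_size,
                   config$initial_state, noise, store_states)
}
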