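## Per-chain RNG streams.
##
## Every chain owns two independent L'Ecuyer-CMRG streams: one that drives the
## Brownian increments and one that drives minibatch subsampling. Keeping the
## two sources on separate streams means switching the stochastic gradient on
## or off never perturbs the noise sequence, and chain i of a larger ensemble
## is bit-for-bit the same as chain i of a smaller one.

#' Derive independent RNG streams from a base seed
#'
#' Creates `n_streams` independent L'Ecuyer-CMRG generator states, derived
#' deterministically from `base_seed` via [parallel::nextRNGStream()]. The
#' global RNG state and kind are left untouched.
#'
#' @param base_seed Integer seed.
#' @param n_streams Number of streams to derive.
#' @return A list of `.Random.seed`-style integer vectors.
#' @export
make_streams <- function(base_seed, n_streams) {
  stopifnot(is.numeric(base_seed), length(base_seed) == 1L, n_streams >= 1)
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_kind <- RNGkind()
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(base_seed %% .Machine$integer.max), kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", envir = globalenv())
  streams <- vector("list", n_streams)
  for (i in seq_len(n_streams)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

## Streams for chain i of an ensemble: element 1 drives noise, element 2
## drives minibatch index draws.
chain_streams <- function(base_seed, n_chains) {
  all <- make_streams(base_seed, 2L * n_chains)
  lapply(seq_len(n_chains), function(i) {
    list(noise = all[[2L * i - 1L]], minibatch = all[[2L * i]])
  })
}

## Evaluate fn() with the RNG positioned at `stream`; returns the value and
## the advanced stream so subsequent draws continue where these left off.
draw_stream <- function(stream, fn) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream, envir = globalenv())
  value <- fn()
  new_stream <- get(".Random.seed", envir = globalenv())
  if (is.null(old_seed)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
  list(value = value, stream = new_stream)
}
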