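# Reproducibility plumbing: named sub-streams derived from one global seed,
# and per-molecule keyed draws that are independent of evaluation order.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named stream seed from a global seed
#'
#' Hashes `(seed, name)` to a non-negative integer below 2^31 so that each
#' consumer of randomness (oracle, acquisition, surrogate, splits) owns an
#' independent stream: changing how one consumer draws does not shift the
#' others.
#'
#' @param seed integer global seed.
#' @param name character stream label.
#' @return a single integer seed.
#' @export
#' @examples
#' streamSeed(1, "oracle") != streamSeed(1, "acquisition")
streamSeed <- function(seed, name) {
  h <- digest::digest2int(paste0(name, "", as.integer(seed)))
  # fold into [0, 2^31 - 1]
  as.integer(abs(h) %% .Machine$integer.max)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Per-molecule keyed draws: one uniform (failure decision) and one standard
# normal (observation noise) per (seed, id) pair. Order-independent by
# construction: the draw depends only on the key, never on call order.
keyedDraws <- function(seed, ids) {
  n <- length(ids)
  u <- numeric(n)
  z <- numeric(n)
  for (i in seq_len(n)) {
    k <- streamSeed(seed, paste0("mol", ids[i]))
    draws <- withSeed(k, c(runif(1L), rnorm(1L)))
    u[i] <- draws[1L]
    z[i] <- draws[2L]
  }
  list(u = u, z = z)
}
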