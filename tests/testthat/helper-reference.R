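# Independent brute-force reference implementation of the synchronous
# update rule, written as plain per-cell loops with no code shared with the
# package internals. Used to cross-check the optimized core on small grids.
# It consumes epsilon trials in the same documented row-major order, so
# stochastic runs under the same seed must match bit for bit.

reference_step <- function(counters, t, sub) {
  L <- sub$L
  tau <- sub$config$tau
  C <- tau + 1L
  eps <- sub$config$epsilon
  pace <- (t %% sub$config$T) == 0
  excited <- counters == C
  new <- counters
  for (y in seq_len(L)) {
    for (x in seq_len(L)) {
      c0 <- counters[x, y]
      if (c0 > 0L) {
        new[x, y] <- c0 - 1L
        next
      }
      new[x, y] <- 0L
      if (sub$ablated[x, y]) next
      yd <- y %% L + 1L
      yu <- (y - 2L) %% L + 1L
      stim <- (x > 1L && excited[x - 1L, y]) ||
        (x < L && excited[x + 1L, y]) ||
        (sub$vertical_edges[x, y] && excited[x, yd]) ||
        (sub$vertical_edges[x, yu] && excited[x, yu])
      fire <- FALSE
      if (stim) {
        fire <- if (sub$dysfunctional[x, y]) stats::runif(1) >= eps else TRUE
      }
      if (pace && x == 1L) fire <- TRUE
      if (fire) new[x, y] <- C
    }
  }
  new
}

reference_run <- function(sub, n_steps, seed) {
  counters <- matrix(0L, sub$L, sub$L)
  n_excited <- integer(n_steps)
  set.seed(seed)
  C <- sub$config$tau + 1L
  for (s in seq_len(n_steps)) {
    counters <- reference_step(counters, s - 1L, sub)
    n_excited[s] <- sum(counters == C)
  }
  list(n_excited = n_excited, counters = counters)
}

# seed of the dynamics RNG stream for a substrate (the documented offset)
dynamics_seed <- function(sub) (sub$seed + 1013904223) %% 2147483647
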