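# Deterministic hand-built substrates for tests and demonstrations.

#' Construct a deterministic test substrate
#'
#' Three scripted substrates with documented layouts:
#' \describe{
#'   \item{\code{"planar"}}{fully coupled, no dysfunction
#'     (\code{nu = 1, delta = 0}): regular planar wave fronts for any
#'     pacing.}
#'   \item{\code{"toy_circuit"}}{the minimal two-cable reentry motif. Two
#'     cables (\code{y = 1, 2}) in an otherwise uncoupled lattice, joined
#'     by vertical edges at columns \code{xd - 1} and \code{xd + ell}
#'     only; the single dysfunctional cell sits at \code{(xd, 2)}. Its
#'     scanned distance is exactly \code{ell}, so the motif is critical
#'     iff \code{ell >= tau / 2}. \code{epsilon = 0} by default: use
#'     [prepare_wavebreak_state()] to realize the conduction block
#'     deterministically.}
#'   \item{\code{"critical_one"}}{a fully coupled sheet containing exactly
#'     one critical region: a corridor of \code{ell} uncoupled cells on
#'     cable \code{yb} starting at the single dysfunctional cell
#'     \code{(xd, yb)}. With \code{epsilon > 0}, paced beats eventually
#'     block at the dysfunctional cell and a rotor forms around the
#'     corridor.}
#' }
#'
#' @param kind one of \code{"planar"}, \code{"toy_circuit"},
#'   \code{"critical_one"}.
#' @param L lattice side length.
#' @param tau refractory period.
#' @param T pacing period.
#' @param ell corridor length (toy_circuit, critical_one).
#' @param xd column of the dysfunctional cell.
#' @param yb cable of the dysfunctional cell (critical_one).
#' @param epsilon failure probability of the dysfunctional cell.
#' @param seed seed stored in the substrate (drives the epsilon trials).
#' @return An \code{af_substrate}.
#' @examples
#' toy <- make_fixture("toy_circuit", ell = 3, tau = 4)
#' find_critical_regions(toy)  # exactly the intended cell, ell = 3
#' @export
make_fixture <- function(kind, L = NULL, tau = NULL, T = NULL, ell = NULL,
                         xd = NULL, yb = NULL, epsilon = NULL,
                         seed = 1L) {
  switch(
    kind,
    planar = {
      if (is.null(L)) L <- 50L
      if (is.null(tau)) tau <- 50L
      if (is.null(T)) T <- 2L * L
      generate_substrate(model_config(L = L, nu = 1, delta = 0,
                                      epsilon = 0, tau = tau, T = T,
                                      seed = seed))
    },
    toy_circuit = {
      if (is.null(tau)) tau <- 4L
      if (is.null(ell)) ell <- 3L
      if (is.null(epsilon)) epsilon <- 0
      ell <- check_count(ell, "ell", min = 1L)
      if (is.null(xd)) xd <- 4L
      if (is.null(L)) L <- max(xd + ell + 3L, 10L)
      if (is.null(T)) T <- 5000L
      if (xd < 2L || xd + ell > L) stop_param("ell", "motif does not fit")
      cfg <- model_config(L = L, nu = 0, delta = 0, epsilon = epsilon,
                          tau = tau, T = T, seed = seed)
      ve <- matrix(FALSE, L, L)
      ve[xd - 1L, 1L] <- TRUE   # left closure, joins cables 1 and 2
      ve[xd + ell, 1L] <- TRUE  # distal connection at distance ell
      dysf <- matrix(FALSE, L, L)
      dysf[xd, 2L] <- TRUE
      sub <- new_substrate(L, ve, dysf, matrix(FALSE, L, L), seed, cfg)
      attr(sub, "motif") <- list(xd = xd, yb = 2L, ell = ell)
      sub
    },
    critical_one = {
      if (is.null(L)) L <- 60L
      if (is.null(T)) T <- 220L
      if (is.null(tau)) tau <- 50L
      if (is.null(ell)) ell <- 30L
      if (is.null(epsilon)) epsilon <- 0.05
      ell <- check_count(ell, "ell", min = 1L)
      if (is.null(xd)) xd <- 15L
      if (is.null(yb)) yb <- L %/% 2L
      if (xd < 2L || xd + ell > L) stop_param("ell", "corridor does not fit")
      # sparse random background (the regime the model lives in), with a
      # scripted two-cable circuit carved into it: corridor cells on cable
      # yb carry no transverse edges, the circuit closes through forced
      # edges joining cables yb - 1 and yb at columns xd - 1 and xd + ell.
      # Only (xd, yb) is dysfunctional, so it is the only possible
      # critical region.
      nu_bg <- 0.14
      cfg <- model_config(L = L, nu = nu_bg, delta = 1 / L^2,
                          epsilon = epsilon, tau = tau, T = T, seed = seed)
      ve <- eval_with_rng(list(seed = seed), function() {
        matrix(stats::runif(L * L) < nu_bg, L, L)
      })$value
      cols <- xd:(xd + ell - 1L)
      yu <- (yb - 2L) %% L + 1L
      ve[cols, yu] <- FALSE  # edges to the cable above
      ve[cols, yb] <- FALSE  # edges to the cable below
      ve[xd - 1L, yu] <- TRUE   # proximal closure of the circuit
      ve[xd + ell, yu] <- TRUE  # distal connection at distance ell
      dysf <- matrix(FALSE, L, L)
      dysf[xd, yb] <- TRUE
      sub <- new_substrate(L, ve, dysf, matrix(FALSE, L, L), seed, cfg)
      attr(sub, "motif") <- list(xd = xd, yb = yb, ell = ell)
      sub
    },
    stop_param("kind", sprintf("unknown fixture kind '%s'", kind)))
}

#' Prepare a mid-wave conduction-block state
#'
#' Builds the tissue state a planar paced wave front would produce at the
#' moment it reaches column \code{x_block}, except that the cell
#' \code{(x_block, y_block)} has just failed to excite (a conduction
#' block). Columns to the left carry the refractory tail of the front.
#' Running the dynamics from this state on a [make_fixture()]
#' \code{"toy_circuit"} substrate with \code{epsilon = 0} realizes the
#' wave-break deterministically: the distal transverse connection feeds a
#' retrograde wave into the blocked cable, and a reentrant circuit forms
#' iff the return path satisfies \code{ell >= tau / 2}.
#'
#' @param substrate an \code{af_substrate}.
#' @param x_block,y_block the blocked cell (defaults: the fixture's
#'   dysfunctional cell).
#' @return An \code{af_state} at time \code{t = x_block}.
#' @export
prepare_wavebreak_state <- function(substrate,
                                    x_block = NULL, y_block = NULL) {
  stopifnot(inherits(substrate, "af_substrate"))
  motif <- attr(substrate, "motif")
  if (is.null(x_block)) x_block <- motif$xd
  if (is.null(y_block)) y_block <- motif$yb
  L <- substrate$L
  tau <- substrate$config$tau
  C <- tau + 1L
  # planar front launched by the t = 0 pacing event: column x excited at
  # step x, so at t = x_block column x carries counter C - (x_block - x)
  counters <- matrix(0L, L, L)
  for (x in seq_len(min(x_block, L))) {
    counters[x, ] <- max(0L, C - (x_block - x))
  }
  counters[x_block, y_block] <- 0L  # the blocked cell stayed resting
  counters[substrate$ablated] <- 0L
  st <- initialize_state(substrate, counters = counters,
                         t0 = as.integer(x_block))
  # the paced beat that launched this front
  st$beats <- 1L
  st$last_excite <- matrix(-1L, L, L)
  for (x in seq_len(min(x_block, L))) st$last_excite[x, ] <- x
  st$last_excite[x_block, y_block] <- -1L
  st
}
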