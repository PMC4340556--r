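#' Probability that a cell has at least one transverse coupling
#'
#' A cell touches two candidate vertical edges (to the cable above and the
#' cable below), each present independently with probability \code{nu}, so
#' \code{p_nu = 1 - (1 - nu)^2}.
#'
#' @param nu transverse coupling probability in [0, 1] (vectorised).
#' @return \code{1 - (1 - nu)^2}.
#' @examples
#' p_transverse(0.18)  # 0.3276
#' @export
p_transverse <- function(nu) {
  check_prob(nu, "nu")
  1 - (1 - nu)^2
}

#' Probability that a dysfunctional cell is harmless
#'
#' For a dysfunctional cell, let \code{ell} be the distance (starting at 0
#' on the cell itself) to the first cell at or to its right with a
#' transverse coupling. A conduction block at the cell can close into a
#' reentrant circuit only if the return path is long enough to outlast the
#' refractory period, i.e. if \code{ell >= tau / 2}. Since \code{ell} is
#' geometric with success probability \code{p_nu = 1 - (1 - nu)^2},
#' \deqn{P(ell < tau/2) = \sum_{l=0}^{tau/2 - 1} (1 - p_nu)^l p_nu
#'   = 1 - (1 - nu)^{tau}.}
#' The closed form is used directly; for odd \code{tau} it interpolates the
#' half-integer cutoff (the scanner's integer criterion \code{ell >= tau/2}
#' then corresponds to \code{ell >= ceiling(tau/2)}).
#'
#' @param nu transverse coupling probability in [0, 1] (vectorised).
#' @param tau refractory period in steps (>= 1; even in the exact
#'   derivation).
#' @return \code{1 - (1 - nu)^tau}.
#' @export
p_short_circuit <- function(nu, tau) {
  check_prob(nu, "nu")
  tau <- check_count(tau, "tau", min = 1L)
  -expm1(tau * log1p(-nu))
}

#' Risk of at least one fibrillation-inducing structure
#'
#' The lattice holds \code{delta * L^2} dysfunctional cells on average,
#' each independently harmless with probability \code{1 - (1 - nu)^tau},
#' so the probability that at least one critical region exists is
#' \deqn{P_{risk} = 1 - [1 - (1 - nu)^{tau}]^{delta L^2}.}
#' Evaluation is in log space (\code{log1p}/\code{expm1}) so exponents in
#' the thousands do not underflow.
#'
#' @param nu transverse coupling probability in [0, 1] (vectorised).
#' @param tau refractory period in steps.
#' @param delta dysfunctional-cell fraction in [0, 1].
#' @param L lattice side length.
#' @return The risk probability.
#' @examples
#' p_risk(0.14, 50, 0.05, 200)  # near the transition, ~0.66
#' @export
p_risk <- function(nu, tau, delta, L) {
  check_prob(nu, "nu")
  tau <- check_count(tau, "tau", min = 1L)
  check_prob(delta, "delta")
  L <- check_count(L, "L", min = 2L)
  p_risk_core(nu, tau, delta * L^2)
}

# shared kernel: risk with real-valued exponents tau_eff and m = mean
# number of dysfunctional cells
p_risk_core <- function(nu, tau_eff, m) {
  q <- exp(tau_eff * log1p(-nu))  # (1 - nu)^tau
  out <- ifelse(q >= 1, ifelse(m > 0, 1, 0), -expm1(m * log1p(-q)))
  pmin(pmax(out, 0), 1)
}

#' Risk in physical units
#'
#' The dimensional form of the structure risk,
#' \deqn{P_{risk} = 1 - [1 - (1-nu)^{\theta_x \tau' / (b \Delta x')}]^
#'   {\delta L'^2 / (b^2 \Delta x' \Delta y')},}
#' whose exponents are the dimensionless refractory period and the mean
#' dysfunctional-cell count (50 and 2000 under the default tissue values).
#'
#' @param phys an [physical_params()] object.
#' @param nu coarse-grained transverse coupling probability (vectorised).
#' @param delta dysfunctional-cell fraction.
#' @return The risk probability.
#' @export
p_risk_physical <- function(phys, nu, delta) {
  stopifnot(inherits(phys, "af_physical"))
  check_prob(nu, "nu")
  check_prob(delta, "delta")
  tau_eff <- phys$theta_x * phys$tau_phys / (phys$b * phys$dx)
  m <- delta * phys$L_phys^2 / (phys$b^2 * phys$dx * phys$dy)
  if (tau_eff <= 0) stop_param("tau_phys", "non-positive refractory exponent")
  if (m < 0) stop_param("delta", "negative cell-count exponent")
  p_risk_core(nu, tau_eff, m)
}

#' Finite-lattice structure risk
#'
#' The closed form [p_risk()] treats every dysfunctional cell as an
#' independent Bernoulli trial on an unbounded cable. On the actual
#' \code{L x L} lattice two finite-size effects depress the probability
#' of observing a critical region: cells near the open right boundary
#' cannot reach a transverse coupling at distance \code{ell >= tau/2}
#' (truncation), and several dysfunctional cells inside one long
#' uncoupled corridor stand or fall together (clustering), so critical
#' cells arrive in bunches rather than independently.
#'
#' This function computes the probability that at least one critical
#' region exists, exactly within a cable, by dynamic programming over
#' the joint law of the coupling indicators and the dysfunction mask
#' (state: distance to the next transversely coupled cell). Cables are
#' treated as independent; the residual correlation through shared
#' vertical edges between neighbouring cables is the only approximation
#' and is negligible against sampling noise at the default parameters.
#' [mc_risk_estimate()] converges to this value, not to [p_risk()]; the
#' difference between the two quantifies the finite-size deficit of the
#' closed form (about 0.10 at the transition for the default
#' \code{L = 200, tau = 50, delta = 0.05}).
#'
#' @param nu transverse coupling probability in [0, 1] (vectorised).
#' @param tau refractory period in steps (criticality cutoff
#'   \code{ell >= tau/2}).
#' @param delta dysfunctional-cell fraction.
#' @param L lattice side length.
#' @return Probability that the lattice contains at least one critical
#'   region.
#' @export
p_risk_finite <- function(nu, tau, delta, L) {
  check_prob(nu, "nu")
  tau <- check_count(tau, "tau", min = 2L)
  check_prob(delta, "delta")
  L <- check_count(L, "L", min = 2L)
  k <- ceiling(tau / 2)
  vapply(nu, function(v) {
    p <- 1 - (1 - v)^2
    # g[j + 1], j = 0..L-1: P(next coupled cell at distance j from the
    # current column, and no critical cell to the right); g[L + 1]: no
    # coupled cell before the boundary
    g <- c(rep(0, L), 1)
    for (x in L:1) {
      gn <- numeric(L + 1)
      gn[1] <- p * sum(g)
      jmax <- L - x + 1L
      shift <- g[seq_len(jmax)]
      phi <- ifelse(seq_len(jmax) >= k, 1 - delta, 1)
      gn[1L + seq_len(jmax)] <- (1 - p) * shift * phi
      gn[L + 1] <- gn[L + 1] + (1 - p) * g[L + 1]
      g <- gn
    }
    min(max(1 - sum(g)^L, 0), 1)
  }, numeric(1))
}

#' Threshold transverse coupling nu-star
#'
#' The point of steepest slope of the risk curve, marking the transition
#' from planar propagation to fibrillation:
#' \deqn{\nu^{\star} \approx 1 - (\delta L^2)^{-1/\tau},}
#' valid for \code{tau >> 1} and \code{delta * L^2 * tau >> 1}. It
#' decreases with increasing refractory period: prolonging refractoriness
#' shrinks the set of couplings that can sustain reentry.
#'
#' @param delta dysfunctional-cell fraction.
#' @param L lattice side length.
#' @param tau refractory period in steps.
#' @return The threshold probability.
#' @examples
#' nu_star(0.05, 200, 50)  # ~0.14
#' @export
nu_star <- function(delta, L, tau) {
  check_prob(delta, "delta")
  L <- check_count(L, "L", min = 2L)
  tau <- check_count(tau, "tau", min = 1L)
  m <- delta * L^2
  if (m <= 1) stop_param("delta", "requires delta * L^2 > 1")
  -expm1(-log(m) / tau)
}

#' Evaluate the analytic risk curve on a grid
#'
#' @param nu_grid vector of coupling probabilities in [0, 1].
#' @param tau refractory period in steps.
#' @param delta dysfunctional-cell fraction.
#' @param L lattice side length.
#' @return A data frame of class \code{af_risk_curve} with columns
#'   \code{nu} and \code{p_risk}, carrying \code{tau}, \code{delta} and
#'   \code{L} as attributes; \code{p_risk} is monotone non-increasing in
#'   \code{nu}.
#' @export
risk_curve <- function(nu_grid, tau, delta, L) {
  check_prob(nu_grid, "nu_grid")
  ord <- order(nu_grid)
  out <- data.frame(nu = nu_grid[ord],
                    p_risk = p_risk(nu_grid[ord], tau, delta, L))
  attr(out, "params") <- list(tau = tau, delta = delta, L = L)
  class(out) <- c("af_risk_curve", "data.frame")
  out
}

#' @export
plot.af_risk_curve <- function(x, ...) {
  p <- attr(x, "params")
  graphics::plot(x$nu, x$p_risk, type = "l", col = "red", lwd = 2,
                 xlab = expression(nu), ylab = expression(P[risk]),
                 main = sprintf("Structure risk (tau = %d, delta = %g, L = %d)",
                                p$tau, p$delta, p$L), ...)
  graphics::abline(v = nu_star(p$delta, p$L, p$tau), lty = 2, col = "grey40")
  invisible(x)
}
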