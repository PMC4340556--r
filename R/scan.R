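# Locating the two-cable critical regions: a dysfunctional cell whose first
# transversely coupled cell at or to its right lies at distance ell >= tau/2,
# so that a conduction block there can close into a reentrant circuit.

# TRUE where a cell touches at least one vertical edge (to the cable above
# or below, wrapping in y).
has_transverse <- function(substrate) {
  ve <- substrate$vertical_edges
  L <- substrate$L
  up <- ve[, c(L, seq_len(L - 1L)), drop = FALSE]  # edge (x, y-1)-(x, y)
  ve | up
}

# L x L matrix of ell distances (NA where no coupled cell exists before the
# right boundary). Columns are processed right to left with a vectorised
# "last seen coupled column" per cable.
ell_matrix <- function(substrate) {
  h <- has_transverse(substrate)
  L <- substrate$L
  out <- matrix(NA_integer_, L, L)
  last <- rep(NA_integer_, L)  # per cable y: nearest coupled column >= x
  for (x in rev(seq_len(L))) {
    hit <- h[x, ]
    last[hit] <- x
    out[x, ] <- last - x
  }
  out
}

#' Distance to the first transversely coupled cell to the right
#'
#' Returns the smallest \code{ell >= 0} such that cell
#' \code{(x + ell, y)} has at least one incident vertical edge (the cell
#' itself counts as offset 0), or \code{NA} if no such cell exists before
#' the open right boundary. Over random substrates this distance follows a
#' geometric law with success probability \code{p_nu = 1 - (1 - nu)^2},
#' truncated at the boundary.
#'
#' @param substrate an \code{af_substrate}.
#' @param x,y cell coordinates (1-based).
#' @return Integer distance or \code{NA}.
#' @export
ell_distance <- function(substrate, x, y) {
  stopifnot(inherits(substrate, "af_substrate"))
  L <- substrate$L
  x <- check_count(x, "x", min = 1L)
  y <- check_count(y, "y", min = 1L)
  if (x > L) stop_param("x", "outside the lattice")
  if (y > L) stop_param("y", "outside the lattice")
  h <- has_transverse(substrate)
  hits <- which(h[x:L, y])
  if (length(hits) == 0L) return(NA_integer_)
  hits[1L] - 1L
}

#' Find the fibrillation-inducing critical regions of a substrate
#'
#' A critical region is a dysfunctional, non-ablated cell whose
#' [ell_distance()] is defined and at least \code{tau / 2} (ties at
#' exactly \code{tau / 2} are critical). Cells with no transversely
#' coupled cell before the right boundary are not critical: without a
#' vertical edge no retrograde circuit can close. Each region carries a
#' suggested lesion bounding box covering both cables of the circuit:
#' from \code{(x - 1, y - 1)}, spanning \code{ell + 2} columns and 3 rows,
#' clipped at the \code{x} boundaries and wrapped in \code{y}.
#'
#' @param substrate an \code{af_substrate}.
#' @param tau refractory period in steps; defaults to the substrate's
#'   configured value.
#' @return A data frame with columns \code{x}, \code{y}, \code{ell},
#'   \code{bbox_x0}, \code{bbox_y0}, \code{bbox_w}, \code{bbox_h}, one row
#'   per critical region, ordered by \code{(y, x)}.
#' @export
find_critical_regions <- function(substrate, tau = substrate$config$tau) {
  stopifnot(inherits(substrate, "af_substrate"))
  tau <- check_count(tau, "tau", min = 2L)
  L <- substrate$L
  ell <- ell_matrix(substrate)
  crit <- substrate$dysfunctional & !substrate$ablated &
    !is.na(ell) & ell >= tau / 2
  idx <- which(crit)
  x <- (idx - 1L) %% L + 1L
  y <- (idx - 1L) %/% L + 1L
  e <- ell[idx]
  bx0 <- pmax(x - 1L, 1L)
  bw <- pmin(x - 1L + e + 1L, L) - bx0 + 1L  # columns x-1 .. x+ell, clipped
  out <- data.frame(x = x, y = y, ell = e,
                    bbox_x0 = bx0, bbox_y0 = (y - 2L) %% L + 1L,
                    bbox_w = bw, bbox_h = rep.int(min(3L, L), length(x)))
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Monte Carlo estimate of the structure risk
#'
#' Generates independent substrates (seeds \code{config$seed + 0:(n-1)})
#' and returns the fraction containing at least one critical region, the
#' simulation-side estimator of [p_risk()]. As \code{n} grows the estimate
#' is consistent with the closed form up to the small deficit from
#' right-boundary truncation of \code{ell}.
#'
#' @param config an [model_config()] object.
#' @param n_substrates number of substrates to draw (>= 1).
#' @return A list of class \code{af_mc_risk} with fields \code{fraction},
#'   \code{se} (binomial standard error), \code{n}, \code{n_regions}
#'   (per-substrate counts), \code{analytic} (the closed-form risk
#'   [p_risk()]) and \code{analytic_finite} (the finite-lattice reference
#'   [p_risk_finite()] the estimator converges to).
#' @export
mc_risk_estimate <- function(config, n_substrates) {
  stopifnot(inherits(config, "af_config"))
  n_substrates <- check_count(n_substrates, "n_substrates", min = 1L)
  counts <- integer(n_substrates)
  for (i in seq_len(n_substrates)) {
    cfg_i <- config
    cfg_i$seed <- (config$seed + i - 1L) %% 2147483647
    sub <- generate_substrate(cfg_i)
    counts[i] <- nrow(find_critical_regions(sub, config$tau))
  }
  f <- mean(counts > 0)
  structure(
    list(fraction = f, se = sqrt(f * (1 - f) / n_substrates),
         n = n_substrates, n_regions = counts,
         analytic = p_risk(config$nu, config$tau, config$delta, config$L),
         analytic_finite = p_risk_finite(config$nu, config$tau,
                                         config$delta, config$L)),
    class = "af_mc_risk")
}

#' @export
print.af_mc_risk <- function(x, ...) {
  cat(sprintf(
    "<af_mc_risk> fraction with >= 1 critical region: %.4f (SE %.4f, n = %d)\n",
    x$fraction, x$se, x$n))
  cat(sprintf("  closed-form risk: %.4f; finite-lattice risk: %.4f\n",
              x$analytic, x$analytic_finite))
  invisible(x)
}
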