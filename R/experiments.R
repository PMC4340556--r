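# Reproduction of the model's computational experiments: classifying
# fibrillatory activity, the phase diagram in nu, and targeted ablation.

#' Classify fibrillatory activity along a trace
#'
#' A step is flagged as fibrillation-like (nonplanar) activity iff
#' \code{n_excited > threshold_factor * L}, strict inequality.
#'
#' A single planar wave front excites at most one cell per cable per step,
#' so regular paced rhythm keeps the count at or below \code{L} -- up to
#' isolated conduction-delay stragglers: a dysfunctional cell that fails
#' repeated trials is re-excited retrogradely one step behind the front,
#' briefly adding a few cells above \code{L} even in perfectly regular
#' rhythm. Genuinely nonplanar activity carries at least a second
#' simultaneous front and pushes counts towards \code{2 L} and beyond.
#' The default factor 1.1 sits between the two regimes; it is exposed
#' because the boundary admits more than one operational definition.
#'
#' @param trace an \code{af_trace} (or a bare vector of excited-cell
#'   counts).
#' @param L lattice side length.
#' @param threshold_factor multiplier on \code{L} (default 1.1).
#' @return Logical vector, one entry per step.
#' @export
af_activity <- function(trace, L, threshold_factor = 1.1) {
  n <- if (inherits(trace, "af_trace")) trace$n_excited else trace
  if (length(n) == 0L) stop("empty trace", call. = FALSE)
  n > threshold_factor * L
}

#' Fraction of a trace spent in fibrillation-like activity
#'
#' @inheritParams af_activity
#' @return Scalar in [0, 1].
#' @export
time_in_af <- function(trace, L, threshold_factor = 1.1) {
  mean(af_activity(trace, L, threshold_factor))
}

#' Locate the first reentry event in a recorded trace
#'
#' Offline detector over recorded activation events: a cell re-excited
#' when no intervening pacemaker firing could have reached it (a wave
#' needs at least \code{x - 1} steps to reach column \code{x}) must have
#' been excited by circulating activity. Returns the earliest such event,
#' or \code{NULL} if none. This recomputes, from the event log, the same
#' criterion the online detector in [run_episode()] applies during the
#' run.
#'
#' @param trace an \code{af_trace} run with \code{record_activations =
#'   TRUE}.
#' @return \code{list(t, x, y)} or \code{NULL}.
#' @export
reentry_detector <- function(trace) {
  stopifnot(inherits(trace, "af_trace"))
  acts <- trace$activations
  if (is.null(acts)) {
    stop("trace has no recorded activations; rerun with record_activations = TRUE",
         call. = FALSE)
  }
  beats <- sort(trace$beats)
  if (nrow(acts) == 0L) return(NULL)
  acts <- acts[order(acts$y, acts$x, acts$t), , drop = FALSE]
  same <- which(acts$y[-1] == acts$y[-nrow(acts)] &
                  acts$x[-1] == acts$x[-nrow(acts)]) + 1L
  if (length(same) == 0L) return(NULL)
  t_prev <- acts$t[same - 1L]
  t_now <- acts$t[same]
  x <- acts$x[same]
  # first pacemaker firing after the previous excitation; the
  # re-excitation is sinus-attributable only if that beat's wave could
  # have covered the x - 1 columns in time
  k <- findInterval(t_prev, beats) + 1L
  has_beat <- k <= length(beats)
  tb <- beats[pmin(k, max(length(beats), 1L))]
  feasible <- has_beat & tb <= t_now & (tb + x - 1L) <= t_now
  bad <- which(!feasible)
  if (length(bad) == 0L) return(NULL)
  i <- bad[which.min(t_now[bad])]
  list(t = t_now[i], x = x[i], y = acts$y[same[i]])
}

#' Sweep the phase diagram in nu
#'
#' For each coupling fraction in \code{nu_grid} and each realization, a
#' fresh substrate (seed \code{config$seed + realization index}, shared
#' across \code{nu} values as common random numbers) is generated and run
#' for \code{n_steps}; the fraction of time spent in fibrillation-like
#' activity, the number of critical regions, and whether reentry was
#' detected are recorded. The defaults (5 realizations of 2e4 steps) are
#' a scaled-down protocol suited to interactive use; pass
#' \code{n_realizations = 50, n_steps = 1e6} for the full experiment.
#'
#' @param nu_grid vector of coupling probabilities.
#' @param n_realizations realizations per grid point.
#' @param n_steps steps per run.
#' @param config base [model_config()]; its \code{nu} is overridden by the
#'   grid.
#' @param threshold_factor passed to [time_in_af()].
#' @return A data frame of class \code{af_sweep} with columns \code{nu},
#'   \code{realization}, \code{seed}, \code{time_in_af}, \code{n_critical},
#'   \code{reentry_detected}; run metadata in \code{attr(, "metadata")}.
#' @export
phase_sweep <- function(nu_grid, n_realizations = 5L, n_steps = 2e4,
                        config = model_config(), threshold_factor = 1.1) {
  check_prob(nu_grid, "nu_grid")
  if (length(nu_grid) == 0L) stop_param("nu_grid", "must be nonempty")
  n_realizations <- check_count(n_realizations, "n_realizations", min = 1L)
  n_steps <- check_count(n_steps, "n_steps", min = 1L)
  rows <- vector("list", length(nu_grid) * n_realizations)
  k <- 0L
  for (nu in nu_grid) {
    for (r in seq_len(n_realizations)) {
      cfg <- config
      cfg$nu <- nu
      cfg$seed <- (config$seed + r) %% 2147483647
      sub <- generate_substrate(cfg)
      tr <- run_episode(sub, n_steps, detect_reentry = TRUE)
      k <- k + 1L
      rows[[k]] <- data.frame(
        nu = nu, realization = r, seed = cfg$seed,
        time_in_af = time_in_af(tr, cfg$L, threshold_factor),
        n_critical = nrow(find_critical_regions(sub)),
        reentry_detected = !is.null(tr$first_reentry))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "metadata") <- list(
    L = config$L, tau = config$tau, delta = config$delta,
    epsilon = config$epsilon, T = config$T, n_steps = n_steps,
    n_realizations = n_realizations, base_seed = config$seed,
    threshold_factor = threshold_factor,
    seed_schedule = "base_seed + realization_index")
  class(out) <- c("af_sweep", "data.frame")
  out
}

#' Mean time in fibrillation per grid point
#'
#' @param sweep an \code{af_sweep}.
#' @return Data frame with columns \code{nu}, \code{mean_time_in_af},
#'   \code{se} (standard error over realizations).
#' @export
summarize_sweep <- function(sweep) {
  stopifnot(inherits(sweep, "af_sweep"))
  agg <- stats::aggregate(time_in_af ~ nu, data = sweep, FUN = mean)
  sds <- stats::aggregate(time_in_af ~ nu, data = sweep,
                          FUN = function(v) stats::sd(v) / sqrt(length(v)))
  data.frame(nu = agg$nu, mean_time_in_af = agg$time_in_af, se = sds$time_in_af)
}

#' Locate the steepest increase of fibrillation time along the sweep
#'
#' Finds the adjacent pair of grid points with the largest drop in mean
#' time-in-fibrillation as \code{nu} increases and returns the pair
#' midpoint, a simulation-side estimate of the transition point
#' [nu_star()].
#'
#' @param sweep an \code{af_sweep}.
#' @return Midpoint \code{nu} of the steepest adjacent-pair change.
#' @export
transition_estimate <- function(sweep) {
  s <- summarize_sweep(sweep)
  s <- s[order(s$nu), , drop = FALSE]
  if (nrow(s) < 2L) stop("need at least two grid points", call. = FALSE)
  d <- diff(s$mean_time_in_af) / diff(s$nu)
  i <- which.min(d)  # largest decrease as nu increases
  (s$nu[i] + s$nu[i + 1L]) / 2
}

#' @export
plot.af_sweep <- function(x, ...) {
  s <- summarize_sweep(x)
  md <- attr(x, "metadata")
  graphics::plot(s$nu, s$mean_time_in_af, pch = 19, col = "blue",
                 xlab = expression(nu), ylab = "time in AF (fraction)",
                 ylim = c(0, 1), ...)
  graphics::arrows(s$nu, pmax(s$mean_time_in_af - s$se, 0),
                   s$nu, pmin(s$mean_time_in_af + s$se, 1),
                   angle = 90, code = 3, length = 0.03, col = "blue")
  curve_nu <- seq(min(s$nu), max(s$nu), length.out = 200)
  graphics::lines(curve_nu,
                  p_risk(curve_nu, md$tau, md$delta, md$L), col = "red")
  invisible(x)
}

#' Targeted ablation experiment
#'
#' Runs the dynamics until sustained reentry is detected (or
#' \code{max_wait} steps elapse), scans the substrate for the critical
#' region nearest the detected reentry core, applies a square lesion
#' centred on that region's dysfunctional cell, continues the run, and
#' reports whether activity returned to the planar paced rhythm (no
#' fibrillation-like activity over the final two pacing cycles).
#'
#' @param substrate an \code{af_substrate}, or \code{NULL} to generate one
#'   from \code{config}.
#' @param config an [model_config()]; required if \code{substrate} is
#'   \code{NULL}. Should lie in the rotor-forming regime (\code{nu} below
#'   [nu_star()]) for reentry to arise.
#' @param max_wait maximum steps to wait for reentry.
#' @param lesion_size side length of the square lesion in cells
#'   (default 20).
#' @param post_steps steps to run after the lesion (default 8 pacing
#'   cycles).
#' @param lesion_center optional \code{c(x, y)} overriding the scanned
#'   target, e.g. to place a deliberately off-target control lesion.
#' @return A list of class \code{af_ablation}: \code{outcome}
#'   (\code{"terminated"}, \code{"persisted"} or \code{"inconclusive"}),
#'   \code{detection} (first reentry event), \code{lesion} (the rectangle
#'   applied), \code{pre_trace} and \code{post_trace} (excited-cell
#'   counts), \code{time_to_termination} (steps from lesion to the last
#'   fibrillation-like step, \code{NA} if activity persisted), and
#'   \code{substrate_post} (the lesioned substrate).
#' @export
ablation_experiment <- function(substrate = NULL, config = NULL,
                                max_wait = 2e4, lesion_size = 20L,
                                post_steps = NULL, lesion_center = NULL) {
  if (is.null(substrate)) {
    stopifnot(inherits(config, "af_config"))
    substrate <- generate_substrate(config)
  }
  cfg <- substrate$config
  L <- substrate$L
  lesion_size <- check_count(lesion_size, "lesion_size", min = 1L)
  if (lesion_size > L) stop_param("lesion_size", "larger than the lattice")
  if (is.null(post_steps)) post_steps <- 8L * cfg$T
  max_wait <- check_count(max_wait, "max_wait", min = 1L)

  pre <- run_episode(substrate, max_wait, detect_reentry = TRUE,
                     stop_at_reentry = TRUE)
  if (is.null(pre$first_reentry)) {
    return(structure(
      list(outcome = "inconclusive", detection = NULL, lesion = NULL,
           pre_trace = pre$n_excited, post_trace = NULL,
           time_to_termination = NA_integer_, substrate_post = substrate),
      class = "af_ablation"))
  }
  det <- pre$first_reentry

  if (is.null(lesion_center)) {
    regions <- find_critical_regions(substrate)
    if (nrow(regions) == 0L) {
      # reentry without a scanned two-cable region (longer motifs exist);
      # fall back to the reentry core itself
      target <- c(det$x, det$y)
    } else {
      dx <- abs(regions$x - det$x)
      dy <- pmin(abs(regions$y - det$y), L - abs(regions$y - det$y))
      target <- unlist(regions[which.min(dx + dy), c("x", "y")])
    }
  } else {
    target <- lesion_center
  }
  half <- lesion_size %/% 2L
  x0 <- min(max(1L, target[1] - half), L - lesion_size + 1L)
  y0 <- (target[2] - half - 1L) %% L + 1L
  lesioned <- apply_lesion(substrate, x0, y0, lesion_size, lesion_size)

  # continue from the stopped state on the lesioned substrate; ablated
  # cells drop to resting and stay there
  state <- pre$final_state
  state$counters[lesioned$ablated] <- 0L
  post <- run_episode(lesioned, post_steps, state = state,
                      detect_reentry = TRUE, detect_all_reentry = TRUE)

  # Outcome is judged by reentrant firing, not by raw excited-cell counts:
  # a paced front detouring around the lesion transiently recruits the
  # lesion shadow and can push n_excited above L without any circulating
  # activity. Termination = no reentry event during the final two pacing
  # cycles of the post-lesion run.
  t_lesion <- state$t
  assess_from <- t_lesion + post_steps - min(2L * cfg$T, post_steps)
  last_re_t <- if (is.null(post$last_reentry)) -1L else post$last_reentry$t
  terminated <- last_re_t < assess_from
  ttt <- if (terminated) max(last_re_t - t_lesion, 0L) else NA_integer_

  tail_len <- min(2L * cfg$T, length(post$n_excited))
  structure(
    list(outcome = if (terminated) "terminated" else "persisted",
         detection = det,
         lesion = list(x0 = x0, y0 = y0, w = lesion_size, h = lesion_size),
         pre_trace = pre$n_excited, post_trace = post$n_excited,
         post_reentry = post$first_reentry,
         post_last_reentry = post$last_reentry,
         n_post_reentry_events = post$n_reentry_events,
         tail_time_in_af = time_in_af(utils::tail(post$n_excited, tail_len), L),
         time_to_termination = ttt, substrate_post = lesioned),
    class = "af_ablation")
}

#' @export
print.af_ablation <- function(x, ...) {
  cat(sprintf("<af_ablation> outcome: %s\n", x$outcome))
  if (!is.null(x$detection)) {
    cat(sprintf("  reentry detected at t = %d, cell (%d, %d)\n",
                x$detection$t, x$detection$x, x$detection$y))
  }
  if (!is.null(x$lesion)) {
    cat(sprintf("  lesion: %dx%d at (%d, %d)\n",
                x$lesion$w, x$lesion$h, x$lesion$x0, x$lesion$y0))
  }
  if (!is.na(x$time_to_termination)) {
    cat(sprintf("  steps from lesion to last AF activity: %d\n",
                x$time_to_termination))
  }
  invisible(x)
}
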