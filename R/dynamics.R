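#' Initialize the tissue state
#'
#' Creates an all-resting state at time \code{t0} on the given substrate.
#' Per-cell counters follow the convention: \code{tau + 1} on the single
#' depolarizing (excited) step, counting down through \code{tau} refractory
#' steps to 0 (resting), so one excitation makes a cell unexcitable for the
#' excited step plus exactly \code{tau} refractory steps. The dynamics RNG
#' stream is seeded from the substrate seed plus the fixed offset
#' 1013904223 (modulo 2^31 - 1), so the substrate draw and the dynamics
#' draws are decoupled but both derive from the single user seed.
#'
#' @param substrate an \code{af_substrate}.
#' @param counters optional \code{L x L} integer matrix of initial counters
#'   (values in \code{0:(tau + 1)}); used to prepare scripted scenarios such
#'   as a conduction block mid-wave. Default: all resting.
#' @param t0 initial time step.
#' @return An object of class \code{af_state}.
#' @export
initialize_state <- function(substrate, counters = NULL, t0 = 0L) {
  stopifnot(inherits(substrate, "af_substrate"))
  L <- substrate$L
  tau <- substrate$config$tau
  if (is.null(counters)) {
    counters <- matrix(0L, L, L)
  } else {
    stopifnot(identical(dim(counters), c(L, L)))
    storage.mode(counters) <- "integer"
    if (any(counters < 0L) || any(counters > tau + 1L)) {
      stop_param("counters", "values must lie in 0:(tau + 1)")
    }
  }
  structure(
    list(counters = counters, t = as.integer(t0),
         rng_seed = (substrate$seed + 1013904223) %% 2147483647,
         rng_state = NULL,
         last_excite = matrix(-1L, L, L),
         beats = integer(0)),
    class = "af_state")
}

check_state <- function(state, substrate) {
  if (!inherits(state, "af_state")) stop("not an af_state", call. = FALSE)
  if (!identical(dim(state$counters), c(substrate$L, substrate$L))) {
    stop("state dimensions do not match substrate", call. = FALSE)
  }
  invisible(state)
}

#' Advance the tissue state by one synchronous step
#'
#' All cells update in parallel from the pre-update state: counters above
#' zero decrement; a resting, non-ablated cell with at least one coupled
#' excited neighbour becomes excited, except that a dysfunctional cell
#' passes a single Bernoulli trial and fails with probability
#' \code{epsilon} (one trial per stimulated cell per step, however many
#' excited neighbours it has, drawn in row-major order); if the pre-update
#' time is a multiple of \code{T}, resting pacemaker cells self-excite
#' unconditionally. Coupled neighbours are the longitudinal neighbours
#' \code{x - 1, x + 1} (within the open boundaries) and the vertical
#' neighbours where an edge exists, wrapping in \code{y}; excitation
#' propagates in every coupled direction, including retrograde.
#'
#' @param state an \code{af_state}.
#' @param substrate the \code{af_substrate} the state lives on.
#' @return The updated \code{af_state}.
#' @export
ca_step <- function(state, substrate) {
  check_state(state, substrate)
  run_core(state, substrate, n_steps = 1L)$state
}

run_core <- function(state, substrate, n_steps, record_snapshots = integer(0),
                     record_activations = FALSE, detect_reentry = FALSE,
                     stop_at_reentry = FALSE, detect_all_reentry = FALSE) {
  cfg <- substrate$config
  rng <- if (is.null(state$rng_state)) list(seed = state$rng_seed)
         else list(state = state$rng_state)
  out <- eval_with_rng(rng, function() {
    .ca_run(state$counters, state$t, substrate$vertical_edges,
            substrate$dysfunctional, substrate$ablated,
            cfg$tau, cfg$T, cfg$epsilon, as.integer(n_steps),
            as.integer(record_snapshots), record_activations,
            detect_reentry, stop_at_reentry, detect_all_reentry,
            state$last_excite, state$beats)
  })
  res <- out$value
  new_state <- structure(
    list(counters = res$counters, t = res$t,
         rng_seed = state$rng_seed, rng_state = out$rng_state,
         last_excite = res$last_excite, beats = res$beats),
    class = "af_state")
  list(result = res, state = new_state)
}

#' Run an episode of the dynamics
#'
#' Applies [ca_step()] \code{n_steps} times (from a fresh all-resting state
#' unless \code{state} is given) and records a trace: the number of excited
#' cells at every step, pacemaker firing times, optional full counter-grid
#' snapshots, optional per-cell activation events, and the first detected
#' reentry event. A fixed substrate seed yields a bit-identical trace.
#'
#' Reentry detection flags the first re-excitation of a cell that cannot be
#' attributed to a fresh pacemaker wave: there is no pacemaker firing time
#' \code{tb} between the cell's two excitations with \code{tb + (x - 1)} at
#' or before the re-excitation time (a wave needs at least \code{x - 1}
#' steps to reach column \code{x}).
#'
#' @param substrate an \code{af_substrate}.
#' @param n_steps number of steps to run (>= 1).
#' @param state optional \code{af_state} to continue from (e.g. after a
#'   lesion); default is [initialize_state()] on the substrate.
#' @param record_snapshots integer vector of time steps at which to store
#'   the full counter grid.
#' @param record_activations logical; store every excitation event
#'   \code{(t, x, y)}. Intended for small runs.
#' @param detect_reentry logical; track re-excitations online.
#' @param stop_at_reentry logical; stop at the end of the step in which the
#'   first reentry event occurs.
#' @param detect_all_reentry logical; keep scanning after the first reentry
#'   event, recording also the last event and the event count (used to
#'   assess whether reentrant activity has ceased by the end of a run).
#' @return An object of class \code{af_trace} with fields \code{n_excited},
#'   \code{t0}, \code{beats}, \code{events}, \code{snapshots},
#'   \code{activations}, \code{first_reentry}, \code{final_state} and
#'   \code{config}.
#' @examples
#' sub <- generate_substrate(model_config(L = 30, nu = 1, delta = 0, tau = 10,
#'                                        T = 60, seed = 1))
#' tr <- run_episode(sub, 120)
#' max(tr$n_excited)  # a planar front excites at most one cell per cable
#' @export
run_episode <- function(substrate, n_steps, state = NULL,
                        record_snapshots = integer(0),
                        record_activations = FALSE,
                        detect_reentry = FALSE,
                        stop_at_reentry = FALSE,
                        detect_all_reentry = FALSE) {
  stopifnot(inherits(substrate, "af_substrate"))
  n_steps <- check_count(n_steps, "n_steps", min = 1L)
  if (is.null(state)) state <- initialize_state(substrate)
  check_state(state, substrate)
  t0 <- state$t
  out <- run_core(state, substrate, n_steps,
                  record_snapshots = record_snapshots,
                  record_activations = record_activations,
                  detect_reentry = detect_reentry,
                  stop_at_reentry = stop_at_reentry,
                  detect_all_reentry = detect_all_reentry)
  res <- out$result
  as_event <- function(v) {
    if (length(v) == 3L) list(t = v[["t"]], x = v[["x"]], y = v[["y"]])
    else NULL
  }
  fr <- as_event(res$first_reentry)
  lr <- as_event(res$last_reentry)
  events <- data.frame(
    t = c(res$beats, if (!is.null(fr)) fr$t),
    kind = c(rep("pacemaker", length(res$beats)),
             if (!is.null(fr)) "reentry"),
    stringsAsFactors = FALSE)
  events <- events[order(events$t), , drop = FALSE]
  activations <- if (record_activations) {
    data.frame(t = res$act_t, x = res$act_x, y = res$act_y)
  } else NULL
  structure(
    list(n_excited = res$n_excited, t0 = t0, steps = res$steps_done,
         beats = res$beats, events = events,
         snapshots = res$snapshots, activations = activations,
         first_reentry = fr, last_reentry = lr,
         n_reentry_events = res$n_reentry_events,
         final_state = out$state,
         config = substrate$config),
    class = "af_trace")
}

#' @export
print.af_trace <- function(x, ...) {
  cat(sprintf("<af_trace> %d steps from t = %d\n", x$steps, x$t0))
  cat(sprintf("  excited cells per step: min %d, max %d, mean %.2f\n",
              min(x$n_excited), max(x$n_excited), mean(x$n_excited)))
  cat(sprintf("  pacemaker firings: %d\n", length(x$beats)))
  if (!is.null(x$first_reentry)) {
    cat(sprintf("  first reentry: t = %d at (%d, %d)\n",
                x$first_reentry$t, x$first_reentry$x, x$first_reentry$y))
  }
  invisible(x)
}
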