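# Internal helpers shared across modules.

# Round half away from zero (base round() rounds half to even, which would
# make borderline physical-to-model conversions depend on parity).
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_param <- function(field, msg) {
  stop(sprintf("invalid parameter '%s': %s", field, msg), call. = FALSE)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_param(field, "must be a probability in [0, 1]")
  }
  invisible(x)
}

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round_half_up(x)) {
    stop_param(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_param(field, "must be strictly positive")
  }
  invisible(x)
}

# Evaluate `fn()` under the package-controlled RNG stream, leaving the
# caller's .Random.seed untouched. `rng` is either list(seed = <int>) for a
# fresh stream or list(state = <.Random.seed vector>) to continue one.
# Returns list(value, rng_state).
eval_with_rng <- function(rng, fn) {
  genv <- globalenv()
  had_old <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had_old) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had_old) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  if (!is.null(rng$state)) {
    assign(".Random.seed", rng$state, envir = genv)
  } else {
    set.seed(rng$seed)
  }
  value <- fn()
  list(value = value, rng_state = get(".Random.seed", envir = genv))
}
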