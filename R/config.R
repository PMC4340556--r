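#' Dimensionless model parameters
#'
#' Bundles the parameters of the excitable-lattice model: the lattice is an
#' \code{L x L} sheet of cells arranged in longitudinal cables; neighbouring
#' cables are coupled at each site with probability \code{nu}; a fraction
#' \code{delta} of cells is dysfunctional and fails to respond to a
#' stimulating excited neighbour with probability \code{epsilon}; an excited
#' cell is unexcitable for one depolarizing step plus \code{tau} refractory
#' steps; the left-boundary pacemaker column self-excites every \code{T}
#' steps.
#'
#' The defaults are the tissue-scale values coarse-grained by a factor
#' \code{b = 5}: \code{L = 200}, \code{tau = 50}, \code{T = 220},
#' \code{delta = epsilon = 0.05}. \code{nu}, the fraction of transverse
#' connections, is the control parameter of the model; its default 0.18 sits
#' in the paroxysmal (self-terminating) regime.
#'
#' @param L lattice side length in cells (integer, >= 2).
#' @param nu transverse-coupling probability per vertical edge, in [0, 1].
#' @param delta fraction of dysfunctional cells, in [0, 1].
#' @param epsilon per-stimulation failure probability of a dysfunctional
#'   cell, in [0, 1].
#' @param tau refractory period in time steps (integer, >= 1).
#' @param T pacing period in time steps (integer, >= 1).
#' @param seed integer seed; all randomness of a simulation derives from it.
#' @return An object of class \code{af_config}.
#' @seealso [physical_params()], [model_config_from_physical()],
#'   [generate_substrate()]
#' @examples
#' cfg <- model_config(L = 100, nu = 0.15)
#' cfg
#' @export
model_config <- function(L = 200L, nu = 0.18, delta = 0.05, epsilon = 0.05,
                         tau = 50L, T = 220L, seed = 1L) {
  L <- check_count(L, "L", min = 2L)
  check_prob(nu, "nu")
  if (length(nu) != 1L) stop_param("nu", "must be a single probability")
  check_prob(delta, "delta")
  check_prob(epsilon, "epsilon")
  tau <- check_count(tau, "tau", min = 1L)
  T <- check_count(T, "T", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(L = L, nu = nu, delta = delta, epsilon = epsilon,
         tau = tau, T = T, seed = seed),
    class = "af_config")
}

#' @export
print.af_config <- function(x, ...) {
  cat("<af_config> excitable-lattice model parameters\n")
  cat(sprintf("  L = %d, nu = %g, delta = %g, epsilon = %g\n",
              x$L, x$nu, x$delta, x$epsilon))
  cat(sprintf("  tau = %d, T = %d, seed = %d\n", x$tau, x$T, x$seed))
  invisible(x)
}

#' Tissue-scale physical parameters
#'
#' Physical quantities describing the atrial sheet the lattice represents.
#' Lengths are in micrometres and times in milliseconds. Myocytes are taken
#' as \code{dx x dy} bricks (length 100 um, diameter 20 um by default), the
#' depolarization time \code{dt} sets the time step, and the longitudinal
#' conduction velocity is fixed at \code{theta_x = dx / dt}. The sheet has
#' side \code{L_phys} (default \code{sqrt(20 cm^2)}). \code{b} is the
#' coarse-graining factor: \code{b} cells are merged into one lattice unit,
#' which rescales times by \code{b * dt} and the transverse coupling by
#' \code{nu -> 1 - (1 - nu)^b}.
#'
#' @param dx myocyte length (um).
#' @param dy myocyte diameter (um).
#' @param dt depolarization time (ms).
#' @param L_phys side length of the atrial sheet (um).
#' @param tau_phys refractory period (ms).
#' @param T_phys pacing period (ms).
#' @param b coarse-graining factor (positive integer).
#' @return An object of class \code{af_physical}; \code{theta_x} (um/ms) is
#'   computed as \code{dx / dt}.
#' @examples
#' phys <- physical_params()
#' phys$theta_x  # ~167 um/ms ~ 0.2 m/s longitudinal conduction velocity
#' @export
physical_params <- function(dx = 100, dy = 20, dt = 0.6,
                            L_phys = sqrt(20) * 1e4,
                            tau_phys = 150, T_phys = 660, b = 5L) {
  for (f in c("dx", "dy", "dt", "L_phys", "tau_phys", "T_phys")) {
    check_positive(get(f), f)
  }
  b <- check_count(b, "b", min = 1L)
  structure(
    list(dx = dx, dy = dy, dt = dt, L_phys = L_phys,
         tau_phys = tau_phys, T_phys = T_phys,
         theta_x = dx / dt, b = b),
    class = "af_physical")
}

#' @export
print.af_physical <- function(x, ...) {
  cat("<af_physical> tissue-scale parameters (um, ms)\n")
  cat(sprintf("  dx = %g, dy = %g, dt = %g, theta_x = %g um/ms\n",
              x$dx, x$dy, x$dt, x$theta_x))
  cat(sprintf("  L_phys = %g um, tau_phys = %g ms, T_phys = %g ms, b = %d\n",
              x$L_phys, x$tau_phys, x$T_phys, x$b))
  invisible(x)
}

#' Coarse-grain the transverse coupling probability
#'
#' Merging \code{b} cells into one lattice unit replaces the per-cell
#' transverse coupling probability by the probability that at least one of
#' the \code{b} fine-scale sites is coupled:
#' \code{nu -> 1 - (1 - nu)^b}.
#'
#' @param nu_fine fine-scale coupling probability in [0, 1] (vectorised).
#' @param b coarse-graining factor (positive integer).
#' @return The coarse-grained probability.
#' @examples
#' coarse_grain_nu(0.05, 5)  # 1 - 0.95^5
#' @export
coarse_grain_nu <- function(nu_fine, b) {
  check_prob(nu_fine, "nu_fine")
  b <- check_count(b, "b", min = 1L)
  1 - (1 - nu_fine)^b
}

#' Convert physical parameters to a dimensionless model configuration
#'
#' The lattice must contain the same number of cells as the physical sheet,
#' \code{L^2 = L_phys^2 / (b^2 dx dy)}, so
#' \code{L = round(L_phys / (b sqrt(dx dy)))}; times are rescaled by the
#' coarse-grained step \code{b dt}: \code{tau = round(tau_phys / (b dt))}
#' and \code{T = round(T_phys / (b dt))}, rounding half away from zero.
#' With the default tissue values and \code{b = 5} this gives
#' \code{L = 200}, \code{tau = 50}, \code{T = 220}; with \code{b = 1},
#' \code{L = 1000}.
#'
#' \code{nu} is taken as already coarse-grained: callers starting from a
#' fine-scale coupling must apply [coarse_grain_nu()] first.
#'
#' @param phys an [physical_params()] object.
#' @param nu coarse-grained transverse coupling probability.
#' @param delta dysfunctional-cell fraction.
#' @param epsilon per-stimulation failure probability.
#' @param seed integer RNG seed.
#' @return An [model_config()] object.
#' @examples
#' model_config_from_physical(physical_params(), nu = 0.18)$L  # 200
#' @export
model_config_from_physical <- function(phys, nu = 0.18, delta = 0.05,
                                       epsilon = 0.05, seed = 1L) {
  stopifnot(inherits(phys, "af_physical"))
  L <- round_half_up(phys$L_phys / (phys$b * sqrt(phys$dx * phys$dy)))
  tau <- round_half_up(phys$tau_phys / (phys$b * phys$dt))
  T <- round_half_up(phys$T_phys / (phys$b * phys$dt))
  if (L < 2) stop_param("L_phys", "lattice collapses to fewer than 2 cells")
  if (tau < 1) stop_param("tau_phys", "refractory period rounds to zero steps")
  if (T < 1) stop_param("T_phys", "pacing period rounds to zero steps")
  model_config(L = L, nu = nu, delta = delta, epsilon = epsilon,
               tau = tau, T = T, seed = seed)
}

#' Read a flat key-value configuration file
#'
#' Parses a plain-text file of \code{key = value} lines (\code{#} starts a
#' comment) into a model configuration. Keys mirror the field names of
#' [model_config()] and [physical_params()]. If any physical key
#' (\code{dx}, \code{dy}, \code{dt}, \code{L_phys}, \code{tau_phys},
#' \code{T_phys}, \code{b}) is present the file is read in physical mode:
#' unspecified physical fields take their defaults and the result is
#' converted with [model_config_from_physical()]. Otherwise dimensionless
#' mode applies and unspecified fields take the [model_config()] defaults,
#' so an empty file yields the default configuration. \code{overrides}
#' (typically command-line flags) take precedence over file values.
#'
#' @param path path to the configuration file, or \code{NULL} for none.
#' @param overrides named list of values overriding the file.
#' @return An [model_config()] object.
#' @export
read_config_file <- function(path = NULL, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_param("path", sprintf("no such file: %s", path))
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(parts) != 2L) {
        stop_param("config", sprintf("cannot parse line: '%s'", ln))
      }
      kv[[trimws(parts[1])]] <- as.numeric(trimws(parts[2]))
    }
  }
  for (nm in names(overrides)) {
    if (!is.null(overrides[[nm]])) kv[[nm]] <- overrides[[nm]]
  }
  phys_keys <- c("dx", "dy", "dt", "L_phys", "tau_phys", "T_phys", "b")
  model_keys <- c("L", "nu", "delta", "epsilon", "tau", "T", "seed")
  unknown <- setdiff(names(kv), c(phys_keys, model_keys))
  if (length(unknown) > 0) {
    stop_param(unknown[1], "unknown configuration key")
  }
  if (any(phys_keys %in% names(kv))) {
    phys <- do.call(physical_params, kv[intersect(names(kv), phys_keys)])
    args <- kv[intersect(names(kv), c("nu", "delta", "epsilon", "seed"))]
    do.call(model_config_from_physical, c(list(phys = phys), args))
  } else {
    do.call(model_config, kv[intersect(names(kv), model_keys)])
  }
}

#' Write a configuration to a flat key-value file
#'
#' @param config an [model_config()] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_config_file <- function(config, path) {
  stopifnot(inherits(config, "af_config"))
  lines <- sprintf("%s = %.15g", names(config),
                   vapply(config, as.numeric, numeric(1)))
  writeLines(lines, path)
  invisible(path)
}
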