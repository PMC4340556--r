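#' Generate an anisotropic branching-cable substrate
#'
#' Builds the fixed coupling topology on which the dynamics run. Cells form
#' \code{L} horizontal cables of length \code{L}; longitudinal couplings
#' between \code{(x, y)} and \code{(x + 1, y)} are always present (open
#' boundaries at \code{x = 1} and \code{x = L}). Each of the \code{L^2}
#' candidate vertical edges between \code{(x, y)} and \code{(x, y + 1)}
#' (wrapping periodically in \code{y}) is present independently with
#' probability \code{nu}. Each cell is dysfunctional independently with
#' probability \code{delta}, so the expected number of dysfunctional cells
#' is \code{delta * L^2}. The ablated mask starts all-false; cells in the
#' pacemaker column \code{x = 1} self-excite every \code{T} steps.
#'
#' Vertical edges are drawn before the dysfunctional mask, so two
#' configurations differing only in \code{delta} (same seed) share the same
#' edge topology. The substrate is a plain immutable value: the only
#' sanctioned modification is [apply_lesion()], which returns a copy.
#'
#' All grid matrices are \code{L x L} and indexed \code{[x, y]}:
#' \code{vertical_edges[x, y]} marks the edge between \code{(x, y)} and
#' \code{(x, y + 1)}, wrapping at \code{y = L}.
#'
#' @param config an [model_config()] object.
#' @return An object of class \code{af_substrate} with fields \code{L},
#'   \code{vertical_edges}, \code{dysfunctional}, \code{ablated},
#'   \code{pacemaker_x}, \code{seed} and \code{config}.
#' @examples
#' sub <- generate_substrate(model_config(L = 50, nu = 0.2, seed = 7))
#' mean(sub$vertical_edges)  # close to 0.2
#' @export
generate_substrate <- function(config) {
  stopifnot(inherits(config, "af_config"))
  L <- config$L
  drawn <- eval_with_rng(list(seed = config$seed), function() {
    edges <- matrix(stats::runif(L * L) < config$nu, L, L)
    dysf <- matrix(stats::runif(L * L) < config$delta, L, L)
    list(edges = edges, dysf = dysf)
  })$value
  new_substrate(L = L, vertical_edges = drawn$edges,
                dysfunctional = drawn$dysf,
                ablated = matrix(FALSE, L, L),
                seed = config$seed, config = config)
}

# Internal constructor; fixtures and the JSON loader use it directly.
new_substrate <- function(L, vertical_edges, dysfunctional, ablated,
                          seed, config) {
  L <- as.integer(L)
  stopifnot(identical(dim(vertical_edges), c(L, L)),
            identical(dim(dysfunctional), c(L, L)),
            identical(dim(ablated), c(L, L)))
  structure(
    list(L = as.integer(L), vertical_edges = vertical_edges,
         dysfunctional = dysfunctional, ablated = ablated,
         pacemaker_x = 1L, seed = as.integer(seed), config = config),
    class = "af_substrate")
}

#' @export
print.af_substrate <- function(x, ...) {
  cat(sprintf("<af_substrate> %d x %d cells, seed %d\n", x$L, x$L, x$seed))
  cat(sprintf("  vertical edges: %d (fraction %.4f)\n",
              sum(x$vertical_edges), mean(x$vertical_edges)))
  cat(sprintf("  dysfunctional cells: %d, ablated cells: %d\n",
              sum(x$dysfunctional), sum(x$ablated)))
  invisible(x)
}

#' Render a rectangular tissue region unexcitable
#'
#' Marks a \code{width x height} rectangle of cells with lower corner
#' \code{(x0, y0)} as ablated, the model analogue of a catheter-ablation
#' lesion. Ablated cells never excite and so conduct nothing. The rectangle
#' wraps periodically in \code{y}; in \code{x} it must lie within the open
#' boundaries. All other substrate fields are untouched and a modified copy
#' is returned.
#'
#' @param substrate an \code{af_substrate}.
#' @param x0,y0 lower corner of the lesion (1-based).
#' @param width,height lesion extent in cells (positive integers).
#' @return A new \code{af_substrate} with the lesion applied.
#' @export
apply_lesion <- function(substrate, x0, y0, width, height) {
  stopifnot(inherits(substrate, "af_substrate"))
  width <- check_count(width, "width", min = 1L)
  height <- check_count(height, "height", min = 1L)
  L <- substrate$L
  x0 <- check_count(x0, "x0", min = 1L)
  if (x0 + width - 1L > L) {
    stop_param("width", "lesion extends past the open x boundary")
  }
  y0 <- check_count(y0, "y0", min = 1L)
  if (y0 > L) stop_param("y0", "outside the lattice")
  ys <- ((y0 - 1L) + seq_len(height) - 1L) %% L + 1L
  out <- substrate
  out$ablated[x0:(x0 + width - 1L), ys] <- TRUE
  out
}

# ---- serialization ---------------------------------------------------------

# Boolean masks are serialized as run-length-encoded bit strings in x-fastest
# (cable-major) order, e.g. "0x12,1x3,0x85": runs of identical bits with
# their lengths. A checksum (number of TRUE cells and the sum of their
# linear indices modulo 2^31 - 1) guards against corrupted runs.

encode_mask <- function(mask) {
  v <- as.integer(mask)
  r <- rle(v)
  list(
    rle = paste(sprintf("%dx%d", r$values, r$lengths), collapse = ","),
    n_true = sum(v),
    checksum = sum(which(v == 1L) %% 2147483647) %% 2147483647)
}

decode_mask <- function(enc, L) {
  runs <- strsplit(enc$rle, ",", fixed = TRUE)[[1]]
  parts <- regmatches(runs, regexec("^([01])x([0-9]+)$", runs))
  if (any(lengths(parts) != 3L)) stop("malformed run-length encoding")
  values <- as.integer(vapply(parts, `[`, character(1), 2L))
  lens <- as.integer(vapply(parts, `[`, character(1), 3L))
  v <- rep(values, lens)
  if (length(v) != L * L) {
    stop(sprintf("mask has %d entries, expected %d", length(v), L * L))
  }
  if (sum(v) != enc$n_true ||
      sum(which(v == 1L) %% 2147483647) %% 2147483647 != enc$checksum) {
    stop("mask checksum mismatch")
  }
  matrix(as.logical(v), L, L)
}

#' Serialize a substrate to JSON
#'
#' Writes a self-contained JSON document (schema version, model parameters,
#' and the three masks run-length encoded with checksums) from which
#' [read_substrate()] reconstructs a bit-identical substrate.
#'
#' @param substrate an \code{af_substrate}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_substrate <- function(substrate, path) {
  stopifnot(inherits(substrate, "af_substrate"))
  cfg <- substrate$config
  doc <- list(
    schema_version = 1L,
    L = substrate$L, nu = cfg$nu, delta = cfg$delta, epsilon = cfg$epsilon,
    tau = cfg$tau, T = cfg$T, seed = substrate$seed,
    vertical_edges = encode_mask(substrate$vertical_edges),
    dysfunctional = encode_mask(substrate$dysfunctional),
    ablated = encode_mask(substrate$ablated))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a substrate from JSON
#'
#' @param path path to a file written by [write_substrate()].
#' @return An \code{af_substrate}.
#' @export
read_substrate <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    stop("unsupported substrate schema version")
  }
  L <- as.integer(doc$L)
  cfg <- model_config(L = L, nu = doc$nu, delta = doc$delta,
                      epsilon = doc$epsilon, tau = doc$tau, T = doc$T,
                      seed = doc$seed)
  new_substrate(L = L,
                vertical_edges = decode_mask(doc$vertical_edges, L),
                dysfunctional = decode_mask(doc$dysfunctional, L),
                ablated = decode_mask(doc$ablated, L),
                seed = doc$seed, config = cfg)
}
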