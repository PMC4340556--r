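# Plain-text export of traces, snapshots and run manifests.

#' Export a trace as CSV
#'
#' Writes one row per step: \code{t} (absolute time) and \code{n_excited}.
#' Comma-separated, header row, UTF-8, '.' decimal separator.
#'
#' @param trace an \code{af_trace}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "af_trace"))
  df <- data.frame(t = trace$t0 + seq_along(trace$n_excited),
                   n_excited = trace$n_excited)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export trace events as JSON
#'
#' Pacemaker firings and the first reentry event, with the configuration
#' the trace was produced under.
#'
#' @param trace an \code{af_trace}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trace_events <- function(trace, path) {
  stopifnot(inherits(trace, "af_trace"))
  doc <- list(t0 = trace$t0, steps = trace$steps,
              events = trace$events,
              first_reentry = trace$first_reentry,
              config = unclass(trace$config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a counter-grid snapshot as plain text
#'
#' Format: a header line \code{"L t"}, then \code{L} rows of \code{L}
#' integers (cable \code{y} per line, columns \code{x = 1..L}
#' space-separated): the per-cell counter values (\code{tau + 1} excited,
#' \code{tau..1} refractory, 0 resting).
#'
#' @param grid an \code{L x L} integer matrix indexed \code{[x, y]}.
#' @param t the time step the snapshot was taken at.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_snapshot <- function(grid, t, path) {
  stopifnot(is.matrix(grid), nrow(grid) == ncol(grid))
  L <- nrow(grid)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", L, as.integer(t)), con)
  for (y in seq_len(L)) {
    writeLines(paste(grid[, y], collapse = " "), con)
  }
  invisible(path)
}

#' Read a snapshot written by [write_snapshot()]
#'
#' @param path path to the snapshot file.
#' @return \code{list(grid, t)}.
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ", fixed = TRUE)[[1]])
  L <- hdr[1]
  if (length(lines) != L + 1L) stop("snapshot has wrong number of rows")
  grid <- matrix(0L, L, L)
  for (y in seq_len(L)) {
    row <- as.integer(strsplit(lines[y + 1L], " ", fixed = TRUE)[[1]])
    if (length(row) != L) stop("snapshot has wrong row length")
    grid[, y] <- row
  }
  list(grid = grid, t = hdr[2])
}

#' Build a run manifest
#'
#' A manifest captures everything needed to reproduce a run: the resolved
#' parameter set, the seed schedule, the package version and the output
#' paths. Runs are exactly reproducible from the manifest alone because
#' all randomness flows from the recorded seeds.
#'
#' @param config an [model_config()] object.
#' @param seeds the seed schedule actually used.
#' @param outputs named character vector/list of output file paths.
#' @param extra optional named list of additional metadata.
#' @return A list of class \code{af_manifest}.
#' @export
run_manifest <- function(config, seeds, outputs = list(), extra = list()) {
  stopifnot(inherits(config, "af_config"))
  structure(
    c(list(schema_version = 1L,
           package = "aflattice",
           version = as.character(utils::packageVersion("aflattice")),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           config = unclass(config),
           seeds = seeds,
           outputs = outputs),
      extra),
    class = "af_manifest")
}

#' Write a manifest as JSON
#'
#' @param manifest an [run_manifest()] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "af_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
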