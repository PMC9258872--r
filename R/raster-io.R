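#' Read a spike raster from CSV
#'
#' The native raster exchange format: a CSV with header
#' \code{neuron_id,time_ms}, one event per row. Events are re-sorted by time
#' on read. An optional YAML sidecar (same path with extension
#' \code{.meta.yaml}) supplies the population size, duration and provenance;
#' without it, both are inferred from the data.
#'
#' @param path CSV file path.
#' @param nNeurons population size; overrides sidecar/inference.
#' @param duration recording length (ms); overrides sidecar/inference.
#' @return a \code{\linkS4class{SpikeRaster}}.
#' @export
readSpikeRaster <- function(path, nNeurons = NULL, duration = NULL) {
  df <- tryCatch(read.csv(path, colClasses = c("integer", "numeric")),
                 warning = function(w) stop("malformed raster file: ",
                                            conditionMessage(w)),
                 error = function(e) stop("malformed raster file: ",
                                          conditionMessage(e)))
  if (!identical(names(df), c("neuron_id", "time_ms")))
    stop("raster CSV must have header neuron_id,time_ms")
  if (any(!is.finite(df$time_ms)) || any(is.na(df$neuron_id)))
    stop("malformed raster row(s): ",
         paste(utils::head(which(!is.finite(df$time_ms) |
                                   is.na(df$neuron_id)), 5), collapse = ", "))
  meta <- list()
  sidecar <- paste0(path, ".meta.yaml")
  if (file.exists(sidecar)) meta <- yaml::read_yaml(sidecar)
  if (is.null(nNeurons))
    nNeurons <- meta$n_neurons %||% (max(df$neuron_id, 0L) + 1L)
  if (is.null(duration))
    duration <- meta$duration_ms %||% (if (nrow(df)) max(df$time_ms) else 1)
  if (nrow(df) && max(df$neuron_id) >= nNeurons)
    stop("neuron_id out of range for declared n_neurons = ", nNeurons)
  SpikeRaster(neuron = df$neuron_id, time = round(df$time_ms, 2),
              nNeurons = nNeurons, duration = duration,
              metadata = meta[setdiff(names(meta),
                                      c("n_neurons", "duration_ms"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a spike raster to CSV
#'
#' Writes the \code{neuron_id,time_ms} CSV (times with 0.01 ms precision)
#' and a YAML sidecar with the population size, duration and metadata, so a
#' read round-trip restores the raster.
#'
#' @param raster a \code{\linkS4class{SpikeRaster}}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeSpikeRaster <- function(raster, path) {
  stopifnot(is(raster, "SpikeRaster"))
  df <- data.frame(neuron_id = raster@neuron,
                   time_ms = sprintf("%.2f", raster@time))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- c(list(n_neurons = raster@nNeurons,
                 duration_ms = raster@duration),
            raster@metadata)
  yaml::write_yaml(lapply(meta, function(x)
    if (is.numeric(x) || is.character(x) || is.logical(x) || is.list(x)) x
    else as.character(x)), paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Write a measures table to CSV
#'
#' One row per (level, interval) with the four fitted measures, in the
#' package's standard column layout.
#'
#' @param results named list of \code{\link{measureSuite}} outputs, one per
#'   level label.
#' @param path output CSV path.
#' @return the written data.frame, invisibly.
#' @export
writeMeasuresTable <- function(results, path) {
  rows <- lapply(names(results), function(lab) {
    per <- results[[lab]]$per_interval
    data.frame(level = seq_along(results)[match(lab, names(results))],
               label = lab, interval = per$interval,
               mean_rate_hz = per$mean_rate_hz, mpc = per$mpc,
               integration_bits = per$integration_bits,
               complexity_bits = per$complexity_bits)
  })
  df <- do.call(rbind, rows)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
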