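#' Spike raster objects
#'
#' A spike raster holds time-stamped spike events for a population of
#' neurons: a data frame with columns `neuron` (1-based flattened lattice
#' index) and `time_ms`, together with the recording `duration` (ms) and the
#' population size `n_neurons`. All analysis metrics (synchrony, firing
#' rate, population spectrum) operate on this container.
#'
#' @param events data frame with integer column `neuron` and numeric column
#'   `time_ms`. Spike times must lie in `(0, duration]` and be strictly
#'   increasing within each neuron.
#' @param duration recording duration in ms.
#' @param n_neurons number of neurons in the population.
#' @return An object of class `spike_raster`.
#' @examples
#' r <- spike_raster(data.frame(neuron = c(1L, 1L, 2L),
#'                              time_ms = c(10, 30, 15)),
#'                   duration = 100, n_neurons = 4)
#' r
#' mean_firing_rate(r)
#' @export
spike_raster <- function(events, duration, n_neurons) {
  stopifnot(is.data.frame(events), all(c("neuron", "time_ms") %in% names(events)),
            duration >= 0, n_neurons >= 1)
  events <- events[order(events$neuron, events$time_ms), c("neuron", "time_ms")]
  events$neuron <- as.integer(events$neuron)
  rownames(events) <- NULL
  if (nrow(events)) {
    if (any(events$neuron < 1L) || any(events$neuron > n_neurons))
      stop("spike events reference neurons outside 1..n_neurons")
    if (any(events$time_ms <= 0) || any(events$time_ms > duration))
      stop("spike times must lie in (0, duration]")
    dup <- unlist(tapply(events$time_ms, events$neuron,
                         function(x) diff(x) <= 0), use.names = FALSE)
    if (any(dup)) stop("per-neuron spike times must be strictly increasing")
  }
  structure(list(events = events, duration = duration,
                 n_neurons = as.integer(n_neurons)),
            class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d neurons, %.1f ms, %d spikes (%.2f Hz mean)\n",
              x$n_neurons, x$duration, nrow(x$events),
              mean_firing_rate(x)))
  invisible(x)
}

#' @export
as.data.frame.spike_raster <- function(x, ...) x$events

#' @rdname spike_raster
#' @param x a `spike_raster`.
#' @param path file path for the delimited text serialization (columns
#'   `neuron_id`, `time_ms`; duration and population size are carried in
#'   `#`-prefixed header lines).
#' @export
write_raster <- function(x, path) {
  stopifnot(inherits(x, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# duration_ms=%.10g", x$duration),
               sprintf("# n_neurons=%d", x$n_neurons),
               "neuron_id\ttime_ms"), con)
  if (nrow(x$events))
    writeLines(sprintf("%d\t%.10g", x$events$neuron, x$events$time_ms), con)
  invisible(path)
}

#' @rdname spike_raster
#' @export
read_raster <- function(path) {
  hdr <- readLines(path, n = 2L)
  duration <- as.numeric(sub("# duration_ms=", "", hdr[1], fixed = TRUE))
  n_neurons <- as.integer(sub("# n_neurons=", "", hdr[2], fixed = TRUE))
  ev <- utils::read.delim(path, skip = 2L, header = TRUE,
                          colClasses = c("integer", "numeric"))
  names(ev) <- c("neuron", "time_ms")
  spike_raster(ev, duration, n_neurons)
}

#' @export
plot.spike_raster <- function(x, ..., pch = ".", xlab = "time (ms)",
                              ylab = "neuron") {
  graphics::plot(x$events$time_ms, x$events$neuron, pch = pch,
                 xlab = xlab, ylab = ylab, xlim = c(0, x$duration),
                 ylim = c(1, x$n_neurons), ...)
  invisible(x)
}

# internal: raster from engine output (0-based ids, 0-based step of spike;
# a spike detected during step t is stamped at time (t+1)*dt)
raster_from_engine <- function(id0, step0, dt, duration, n_neurons) {
  spike_raster(data.frame(neuron = id0 + 1L, time_ms = (step0 + 1) * dt),
               duration = duration, n_neurons = n_neurons)
}
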