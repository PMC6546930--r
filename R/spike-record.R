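#' Spike records
#'
#' A `spike_record` holds timestamped spike events from a simulated liquid or
#' from an encoder: parallel vectors of neuron indices (1-based) and spike
#' times in ms, sorted by time (ties by neuron index), plus the total
#' simulated duration and the population size.
#'
#' @param neuron integer vector of neuron indices in `1..n_neurons`.
#' @param time numeric vector of spike times in ms, within `[0, duration]`.
#' @param duration total simulated time T, ms.
#' @param n_neurons size of the emitting population.
#' @return an object of class `spike_record`.
#' @examples
#' r <- spike_record(c(1, 2, 1), c(5, 2.5, 10), duration = 20, n_neurons = 3)
#' n_spikes(r)
#' @export
spike_record <- function(neuron = integer(), time = numeric(),
                         duration, n_neurons) {
  stopifnot(length(neuron) == length(time),
            is.numeric(duration), length(duration) == 1L, duration >= 0,
            is_count(n_neurons, min = 0L))
  neuron <- as.integer(neuron)
  time <- as.double(time)
  if (length(time)) {
    if (any(!is.finite(time)) || any(time < 0) || any(time > duration))
      stop_liquidens("spike times must lie in [0, duration]", "invalid_record")
    if (any(neuron < 1L) || any(neuron > n_neurons))
      stop_liquidens("neuron index outside population", "invalid_record")
    o <- order(time, neuron)
    neuron <- neuron[o]
    time <- time[o]
  }
  structure(list(neuron = neuron, time = time,
                 duration = as.double(duration),
                 n_neurons = as.integer(n_neurons)),
            class = "spike_record")
}

#' @rdname spike_record
#' @param x a `spike_record`.
#' @export
n_spikes <- function(x) {
  stopifnot(inherits(x, "spike_record"))
  length(x$time)
}

#' @export
print.spike_record <- function(x, ...) {
  cat(sprintf("<spike_record> %d spikes from %d neurons over %g ms\n",
              length(x$time), x$n_neurons, x$duration))
  invisible(x)
}

#' Write / read a spike record as CSV with a JSON sidecar
#'
#' The CSV has header `neuron_id,time_ms`; the sidecar `<path>.json` stores
#' `{duration_ms, population_size}`. The reader rejects unsorted or
#' out-of-range events.
#'
#' @param x a [spike_record()].
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_spike_record()` returns `path` invisibly;
#'   `read_spike_record()` returns a `spike_record`.
#' @export
write_spike_record <- function(x, path) {
  stopifnot(inherits(x, "spike_record"))
  df <- data.frame(neuron_id = x$neuron, time_ms = x$time)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(duration_ms = x$duration,
                            population_size = x$n_neurons),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spike_record
#' @export
read_spike_record <- function(path) {
  df <- read.csv(path)
  if (!identical(names(df), c("neuron_id", "time_ms")))
    stop_liquidens("spike record CSV must have header neuron_id,time_ms",
                   "invalid_record")
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.unsorted(df$time_ms))
    stop_liquidens("spike record events are not sorted by time",
                   "invalid_record")
  spike_record(df$neuron_id, df$time_ms,
               duration = meta$duration_ms, n_neurons = meta$population_size)
}
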