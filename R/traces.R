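#' Uniformly sampled time series of membrane voltage
#'
#' Light containers used throughout the package: a trace is a numeric vector
#' of samples together with its sampling period `dt` (ms) and start time `t0`
#' (ms). Voltage is in mV, current in uA (per 1 cm^2 soma).
#'
#' @param values numeric vector of samples (mV for voltage, uA for current).
#' @param dt sampling period in ms (> 0).
#' @param t0 time of the first sample in ms.
#' @return an object of class `voltage_trace` or `current_trace` (both inherit
#'   from `trace`).
#' @export
voltage_trace <- function(values, dt, t0 = 0) {
  new_trace(values, dt, t0, "voltage_trace")
}

#' @rdname voltage_trace
#' @export
current_trace <- function(values, dt, t0 = 0) {
  new_trace(values, dt, t0, "current_trace")
}

new_trace <- function(values, dt, t0, class) {
  values <- as.numeric(values)
  stopifnot(is.numeric(dt), length(dt) == 1, dt > 0)
  if (!all(is.finite(values))) stop("trace values must be finite")
  structure(list(values = values, dt = dt, t0 = t0),
            class = c(class, "trace"))
}

#' @export
print.trace <- function(x, ...) {
  unit <- if (inherits(x, "voltage_trace")) "mV" else "uA"
  if (length(x$values) == 0) {
    cat(sprintf("<%s> empty, dt = %g ms\n", class(x)[1], x$dt))
    return(invisible(x))
  }
  cat(sprintf("<%s> %d samples, dt = %g ms, span [%g, %g] ms, range [%.3g, %.3g] %s\n",
              class(x)[1], length(x$values), x$dt, x$t0,
              x$t0 + (length(x$values) - 1) * x$dt,
              min(x$values), max(x$values), unit))
  invisible(x)
}

#' @export
length.trace <- function(x) length(x$values)

#' Sample times of a trace
#' @param x a trace.
#' @return numeric vector of times in ms.
#' @export
trace_times <- function(x) {
  x$t0 + (seq_along(x$values) - 1) * x$dt
}

#' @export
as.data.frame.trace <- function(x, ...) {
  data.frame(time_ms = trace_times(x), value = x$values)
}

#' Decimate a trace by an integer factor
#'
#' Keeps every `factor`-th sample (starting from the first), multiplying the
#' sampling period accordingly. Used to reduce simulation output from the
#' integration grid (0.02 ms) to the 10 kHz (0.1 ms) grid at which the
#' forecasting model and controller operate.
#'
#' @param trace a `voltage_trace` or `current_trace`.
#' @param factor integer >= 1.
#' @return a trace of the same class with `dt * factor`.
#' @export
downsample <- function(trace, factor) {
  stopifnot(inherits(trace, "trace"))
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stop("factor must be a single integer >= 1")
  vals <- trace$values[seq(1, length(trace$values), by = factor)]
  new_trace(vals, trace$dt * factor, trace$t0, class(trace)[1])
}

#' Spike train: ordered spike times
#'
#' @param times numeric vector of spike times in ms, strictly increasing.
#' @return an object of class `spike_train`.
#' @export
spike_train <- function(times = numeric(0)) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("spike times must be strictly increasing")
  structure(list(times = times), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", length(x$times)))
  if (length(x$times) > 0)
    cat(sprintf(" in [%.2f, %.2f] ms", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$times)

#' Detect spikes by upward threshold crossing
#'
#' A spike is recorded at each sample where the voltage is at or above the
#' threshold and the previous sample was below it. The default 30 mV threshold
#' is well above subthreshold fluctuations, so crossings are naturally
#' separated by repolarization and no refractory window is imposed.
#'
#' @param v a `voltage_trace`.
#' @param threshold detection threshold in mV.
#' @return a `spike_train` of crossing times (ms).
#' @export
detect_spikes <- function(v, threshold = 30) {
  stopifnot(inherits(v, "voltage_trace"))
  x <- v$values
  if (length(x) < 2) return(spike_train())
  up <- which(x[-1] >= threshold & x[-length(x)] < threshold) + 1L
  spike_train(v$t0 + (up - 1) * v$dt)
}

#' Read and write traces as two-column CSV (time_ms, value)
#'
#' @param trace a trace object.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param type `"voltage"` or `"current"`.
#' @export
read_trace_csv <- function(path, type = c("voltage", "current")) {
  type <- match.arg(type)
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("expected a two-column CSV (time_ms, value)")
  t <- df[[1]]
  dt <- if (length(t) > 1) stats::median(diff(t)) else 1
  ctor <- if (type == "voltage") voltage_trace else current_trace
  ctor(df[[2]], dt = dt, t0 = t[1])
}

#' Read and write spike trains as one-column CSV of times (ms)
#' @param spikes a `spike_train`.
#' @param path file path.
#' @export
write_spikes_csv <- function(spikes, path) {
  utils::write.csv(data.frame(time_ms = spikes$times), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  df <- utils::read.csv(path)
  spike_train(df[[1]])
}
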