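#' Uniformly sampled trace
#'
#' The package's basic signal container: a vector of values sampled at a
#' constant rate, with an absolute start time.  Used for stimulus waveforms,
#' per-channel ADC reads, and virtual-digitizer captures.
#'
#' @param values numeric vector of sample values (volts, or ADC counts for
#'   device-side traces; see `units`).
#' @param rate sampling rate in Hz.
#' @param start_time absolute time of the first sample, in seconds.
#' @param units free-text unit label, `"V"` by default.
#' @return an object of class `digitized_trace`.
#' @seealso [trace_times()], [analog_source()], [digitize()]
#' @export
#' @examples
#' tr <- digitized_trace(sin(2 * pi * 5 * (0:99) / 100), rate = 100)
#' trace_duration(tr)
digitized_trace <- function(values, rate, start_time = 0, units = "V") {
  stopifnot(is.numeric(values) || is.logical(values),
            length(rate) == 1, is.finite(rate), rate > 0,
            length(start_time) == 1, is.finite(start_time))
  structure(
    list(values = as.numeric(values), rate = as.numeric(rate),
         start_time = as.numeric(start_time), units = as.character(units)[1]),
    class = "digitized_trace"
  )
}

#' Sample times of a trace
#'
#' @param trace a [digitized_trace()].
#' @return numeric vector of absolute sample times in seconds.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "digitized_trace"))
  trace$start_time + (seq_along(trace$values) - 1) / trace$rate
}

#' Duration of a trace
#'
#' @param trace a [digitized_trace()].
#' @return duration in seconds (`length(values) / rate`).
#' @export
trace_duration <- function(trace) length(trace$values) / trace$rate

#' @export
print.digitized_trace <- function(x, ...) {
  cat(sprintf("<digitized_trace> %d samples @ %g Hz (%.6g s), start %.6g s, units %s\n",
              length(x$values), x$rate, trace_duration(x), x$start_time, x$units))
  invisible(x)
}

#' @export
as.data.frame.digitized_trace <- function(x, ...) {
  data.frame(time = trace_times(x), value = x$values)
}

#' Continuous view of an analog source
#'
#' The device model and the virtual digitizer both sample *continuous* analog
#' sources at their own instants.  A source is either a plain R function of
#' time (seconds -> volts) or a [digitized_trace()], which is interpreted
#' through linear interpolation (the idealized reconstruction of, e.g., a
#' soundcard output).  Outside the trace's support the boundary values are
#' held constant.
#'
#' @param x a function of time, or a `digitized_trace`.
#' @return a vectorized function `f(t)` returning values at times `t` (s).
#' @export
analog_source <- function(x) {
  if (is.function(x)) return(x)
  stopifnot(inherits(x, "digitized_trace"))
  n <- length(x$values)
  if (n == 0L) return(function(t) rep(0, length(t)))
  if (n == 1L) { v <- x$values[1]; return(function(t) rep(v, length(t))) }
  stats::approxfun(trace_times(x), x$values,
                   yleft = x$values[1], yright = x$values[n])
}
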