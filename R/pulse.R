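#' Pulse train on one output line
#'
#' Ordered rising/falling edge times of a single digital output line, at
#' exact (unquantized) times in seconds.  Levels strictly alternate starting
#' with a rising edge; an unterminated final pulse is carried with `fall = NA`
#' and `open_end = TRUE`.
#'
#' @param rise numeric vector of rising-edge times (s), strictly increasing.
#' @param fall numeric vector of falling-edge times (s); same length as
#'   `rise`, with a trailing `NA` permitted when `open_end = TRUE`.
#' @param line_id identifier of the output line.
#' @param open_end logical; `TRUE` when the last pulse never terminated
#'   within the observed interval.
#' @return an object of class `pulse_train`.
#' @seealso [pulse_durations()], [edge_times()], [render_pulse_train()]
#' @export
pulse_train <- function(rise, fall = numeric(0), line_id = "out",
                        open_end = FALSE) {
  rise <- as.numeric(rise); fall <- as.numeric(fall)
  if (open_end && length(fall) == length(rise) - 1L) fall <- c(fall, NA_real_)
  stopifnot(length(fall) == length(rise))
  if (length(rise) > 1L) {
    stopifnot(all(diff(rise) > 0))
    closed <- fall[-length(fall)]
    stopifnot(all(is.finite(closed)), all(closed > rise[-length(rise)]),
              all(closed <= rise[-1L]))
  }
  if (length(rise) >= 1L) {
    last <- fall[length(fall)]
    stopifnot(is.na(last) == open_end || !open_end)
    if (!is.na(last)) stopifnot(last > rise[length(rise)])
  }
  structure(list(rise = rise, fall = fall, line_id = line_id,
                 open_end = isTRUE(open_end)),
            class = "pulse_train")
}

#' Number of pulses in a train
#' @param x a [pulse_train()].
#' @export
n_pulses <- function(x) { stopifnot(inherits(x, "pulse_train")); length(x$rise) }

#' Pulse onset times
#' @param x a [pulse_train()].
#' @return rising-edge times in seconds.
#' @export
pulse_onsets <- function(x) { stopifnot(inherits(x, "pulse_train")); x$rise }

#' Pulse durations
#' @param x a [pulse_train()].
#' @return fall minus rise times, in seconds (`NA` for an open final pulse).
#' @export
pulse_durations <- function(x) { stopifnot(inherits(x, "pulse_train")); x$fall - x$rise }

#' Interleaved edge table
#'
#' @param x a [pulse_train()].
#' @return data frame with columns `time` (s) and `level` (`"high"`/`"low"`),
#'   strictly increasing in time and strictly alternating in level.
#' @export
pulse_edges <- function(x) {
  stopifnot(inherits(x, "pulse_train"))
  n <- length(x$rise)
  if (n == 0L) return(data.frame(time = numeric(0), level = character(0)))
  t <- as.vector(rbind(x$rise, x$fall))
  lv <- rep(c("high", "low"), n)
  keep <- !is.na(t)
  data.frame(time = t[keep], level = lv[keep])
}

#' @export
print.pulse_train <- function(x, ...) {
  cat(sprintf("<pulse_train> line '%s': %d pulse(s)%s\n", x$line_id,
              n_pulses(x), if (x$open_end) " (last unterminated)" else ""))
  if (n_pulses(x) > 0L) {
    d <- pulse_durations(x)
    cat(sprintf("  first onset %.6f s, last onset %.6f s, median duration %s s\n",
                x$rise[1], x$rise[length(x$rise)],
                format(stats::median(d, na.rm = TRUE))))
  }
  invisible(x)
}

#' @export
as.data.frame.pulse_train <- function(x, ...) {
  data.frame(onset = x$rise, duration = x$fall - x$rise,
             trial_type = rep(as.character(x$line_id), length(x$rise)))
}

#' Render a pulse train as a logic-level trace
#'
#' The virtual digitizer's view of a TTL line: samples on a uniform grid are
#' `high` volts whenever some pulse satisfies `rise <= t < fall`, else `low`.
#'
#' @param train a [pulse_train()].
#' @param rate digitizer sampling rate in Hz.
#' @param duration capture duration in seconds.
#' @param high,low logic levels in volts (3.3 / 0 by default).
#' @param start_time capture start, seconds.
#' @return a [digitized_trace()] of voltages.
#' @export
render_pulse_train <- function(train, rate, duration, high = 3.3, low = 0,
                               start_time = 0) {
  stopifnot(inherits(train, "pulse_train"), rate > 0, duration >= 0)
  n <- round(duration * rate)
  t <- start_time + (seq_len(n) - 1) / rate
  fall <- train$fall
  if (train$open_end && length(fall)) fall[length(fall)] <- Inf
  lev <- findInterval(t, train$rise) - findInterval(t, fall)
  digitized_trace(ifelse(lev > 0, high, low), rate, start_time)
}
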