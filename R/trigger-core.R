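#' Trigger channel configuration
#'
#' Per-channel parameters of the firmware's onset-detecting `Trigger` logic.
#' A trigger samples one analog input, compares each sample against a raw ADC
#' threshold, and drives an output pulse whose timing is governed by three
#' durations:
#'
#' * `min_pulse_duration` — minimum time between the initial threshold
#'   crossing and termination of the output pulse;
#' * `pulse_increment` — minimum time between the *most recent* threshold
#'   crossing and termination (the hold time: with 0 the pulse has fixed
#'   duration, with more the pulse rides through gaps in the input);
#' * `refractory_period` — minimum time between one output-pulse onset and
#'   the next (de-bounces the trigger output).
#'
#' All three are evaluated only at sample ticks, so realized durations are
#' quantized to the sample period.
#'
#' @param sampling_frequency sampling rate in Hz.
#' @param threshold detection threshold in raw ADC counts (0–1023 for the
#'   default 10-bit converter).  The comparison is strict: a sample is
#'   supra-threshold iff `sample > threshold`.
#' @param min_pulse_duration,pulse_increment,refractory_period durations
#'   in microseconds, all `>= 0`.
#' @param mode `"oscillatory"` for audio-like inputs or `"dc"` for slowly
#'   varying inputs such as light sensors.  Both use the same supra-threshold
#'   onset logic; `"dc"` additionally honours `polarity`.
#' @param polarity for `"dc"` mode, whether onsets are rising or falling
#'   crossings of the threshold.
#' @return an object of class `trigger_config`.
#' @export
#' @examples
#' cfg <- trigger_config(6250, threshold = 50, min_pulse_duration = 10000)
trigger_config <- function(sampling_frequency, threshold = 50,
                           min_pulse_duration = 10000, pulse_increment = 0,
                           refractory_period = 100000,
                           mode = c("oscillatory", "dc"),
                           polarity = c("rising", "falling")) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  stopifnot(length(sampling_frequency) == 1, sampling_frequency > 0,
            length(threshold) == 1, threshold >= 0, threshold <= 1023,
            min_pulse_duration >= 0, pulse_increment >= 0,
            refractory_period >= 0)
  structure(list(sampling_frequency = as.numeric(sampling_frequency),
                 threshold = as.numeric(threshold),
                 min_pulse_duration = as.numeric(min_pulse_duration),
                 pulse_increment = as.numeric(pulse_increment),
                 refractory_period = as.numeric(refractory_period),
                 mode = mode, polarity = polarity),
            class = "trigger_config")
}

#' Switch channel configuration
#'
#' Parameters for de-bounced switch-closure detection (button presses,
#' nurse-call cords and similar).  One event is registered per closure whose
#' closed state persists at least `debounce_time`; subsequent events are
#' gated by `refractory_period`.  Each event emits an output pulse of
#' `pulse_duration` (the de-bounce spec does not constrain the output width,
#' so it is a plain parameter here).
#'
#' @param debounce_time minimum stable closure, µs (default 20 ms, typical
#'   mechanical bounce scale).
#' @param refractory_period minimum event-to-event interval, µs.
#' @param pulse_duration output pulse width, µs.
#' @return an object of class `switch_config`.
#' @export
switch_config <- function(debounce_time = 20000, refractory_period = 1e5,
                          pulse_duration = 10000) {
  stopifnot(debounce_time >= 0, refractory_period >= 0, pulse_duration > 0)
  structure(list(debounce_time = as.numeric(debounce_time),
                 refractory_period = as.numeric(refractory_period),
                 pulse_duration = as.numeric(pulse_duration)),
            class = "switch_config")
}

#' Fresh trigger state
#'
#' @return the idle state consumed and produced by [trigger_step()].
#' @export
new_trigger_state <- function() {
  list(phase = "idle", last_onset_time = NULL, last_supra_time = NULL,
       pulse_start_time = NULL, last_time = NULL)
}

# comparison slack for tick-time arithmetic, in µs (1 ps)
.t_eps <- 1e-6

.supra <- function(config, sample) {
  if (config$mode == "dc" && config$polarity == "falling")
    sample < config$threshold
  else
    sample > config$threshold
}

#' Advance the trigger state machine by one sample
#'
#' Evaluates the firmware's per-tick logic at one sample instant.  At each
#' tick, in order: while in a pulse, a supra-threshold sample refreshes the
#' last-crossing time, then termination fires when *both* the minimum
#' duration (from pulse start) and the increment (from the last crossing)
#' have elapsed; while idle, a supra-threshold sample starts a pulse unless
#' the refractory period since the previous onset has not yet elapsed
#' (suppression is silent).  Termination is evaluated before new-onset logic,
#' so a still-supra sample at a termination tick never re-triggers at that
#' same tick.
#'
#' @param config a [trigger_config()].
#' @param state state list from [new_trigger_state()] or a previous call.
#' @param sample one ADC reading (counts).
#' @param t sample time in microseconds; must exceed the previous call's `t`.
#' @return `list(state = <new state>, output = NA or "high" or "low")`.
#' @seealso [run_trigger()] for the whole-trace (compiled) equivalent.
#' @export
trigger_step <- function(config, state, sample, t) {
  stopifnot(inherits(config, "trigger_config"))
  if (!is.null(state$last_time) && t <= state$last_time)
    stop("trigger_step: sample time must be strictly increasing (got ",
         t, " after ", state$last_time, ")")
  out <- NA_character_
  supra <- .supra(config, sample)
  if (identical(state$phase, "in_pulse")) {
    if (supra) state$last_supra_time <- t
    if (t - state$pulse_start_time >= config$min_pulse_duration - .t_eps &&
        t - state$last_supra_time >= config$pulse_increment - .t_eps) {
      state$phase <- "idle"
      state$pulse_start_time <- NULL
      out <- "low"
    }
  } else if (supra &&
             (is.null(state$last_onset_time) ||
              t - state$last_onset_time >= config$refractory_period - .t_eps)) {
    state$phase <- "in_pulse"
    state$pulse_start_time <- t
    state$last_supra_time <- t
    state$last_onset_time <- t
    out <- "high"
  }
  state$last_time <- t
  list(state = state, output = out)
}

#' Run a trigger over a sampled trace
#'
#' Folds the [trigger_step()] semantics over every sample of `trace`
#' (compiled inner loop) and collects the output edges.  Sample `i` is taken
#' at time `start_time + (i-1)/rate`; edges carry those exact times.
#'
#' @param config a [trigger_config()]; its `sampling_frequency` must match
#'   the trace rate.
#' @param trace a [digitized_trace()] of ADC counts.
#' @param line_id label for the output line.
#' @return a [pulse_train()] (empty for an empty or never-crossing trace).
#' @export
run_trigger <- function(config, trace, line_id = "out") {
  stopifnot(inherits(config, "trigger_config"), inherits(trace, "digitized_trace"))
  if (abs(trace$rate - config$sampling_frequency) >
      1e-6 * config$sampling_frequency)
    stop("run_trigger: trace rate (", trace$rate,
         " Hz) does not match config sampling_frequency (",
         config$sampling_frequency, " Hz)")
  if (length(trace$values) == 0L)
    return(pulse_train(numeric(0), numeric(0), line_id = line_id))
  v <- trace$values
  thr <- config$threshold
  if (config$mode == "dc" && config$polarity == "falling") { v <- -v; thr <- -thr }
  res <- trigger_scan_cpp(v, trace$start_time * 1e6, 1e6 / trace$rate,
                          thr, config$min_pulse_duration,
                          config$pulse_increment, config$refractory_period)
  pulse_train(res$rise / 1e6, res$fall / 1e6, line_id = line_id,
              open_end = isTRUE(res$open))
}

#' Run de-bounced switch detection over a logic trace
#'
#' Registers one event per switch closure whose closed state persists at
#' least `debounce_time` (span from the first to the last sample of the
#' stable closed run); the event is stamped at the first closure of that
#' run.  Events are then gated so consecutive onsets are at least
#' `refractory_period` apart.
#'
#' @param config a [switch_config()].
#' @param trace a [digitized_trace()] of logic levels; values `> 0.5` are
#'   treated as closed.
#' @param line_id label for the output line.
#' @return a [pulse_train()] with one `pulse_duration`-wide pulse per event.
#' @export
run_switch <- function(config, trace, line_id = "out") {
  stopifnot(inherits(config, "switch_config"), inherits(trace, "digitized_trace"))
  closed <- trace$values > 0.5
  if (!length(closed) || !any(closed))
    return(pulse_train(numeric(0), numeric(0), line_id = line_id))
  r <- rle(closed)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  dt_us <- 1e6 / trace$rate
  stable <- r$values & ((r$lengths - 1L) * dt_us >= config$debounce_time - .t_eps)
  t_us <- trace$start_time * 1e6 + (run_start[stable] - 1L) * dt_us
  keep_t <- numeric(0)
  last <- -Inf
  for (t in t_us) {
    if (t - last >= config$refractory_period - .t_eps) {
      keep_t <- c(keep_t, t)
      last <- t
    }
  }
  rise <- keep_t
  fall <- keep_t + config$pulse_duration
  if (length(rise) > 1L) {
    # overlapping output pulses (refractory shorter than the pulse) merge
    mr <- rise[1]; mf <- fall[1]
    for (i in 2:length(rise)) {
      k <- length(mr)
      if (rise[i] <= mf[k]) mf[k] <- fall[i]
      else { mr <- c(mr, rise[i]); mf <- c(mf, fall[i]) }
    }
    rise <- mr; fall <- mf
  }
  pulse_train(rise / 1e6, fall / 1e6, line_id = line_id)
}
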