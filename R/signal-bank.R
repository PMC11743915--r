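#' Abrupt-onset test tone
#'
#' The latency bench's stimulus: a cosine-phase sinusoid (so the very first
#' sample sits at `+amplitude` — the most abrupt onset a band-limited
#' playback chain can deliver) that tapers away to silence by `total` ms.
#' The envelope is flat for the first half of the stimulus and then decays
#' as a raised cosine to zero.
#'
#' @param f0 carrier frequency, Hz.
#' @param amplitude peak amplitude, volts.
#' @param total stimulus duration, ms.
#' @param rate sampling rate, Hz (standard audio rate by default); must
#'   exceed `2 * f0`.
#' @return a [digitized_trace()].
#' @export
#' @examples
#' tone <- onset_tone()
#' tone$values[1]   # +1: cosine phase
onset_tone <- function(f0 = 100, amplitude = 1, total = 100, rate = 44100) {
  stopifnot(f0 > 0, rate > 2 * f0, total > 0, amplitude >= 0)
  n <- round(total / 1000 * rate)
  t <- (seq_len(n) - 1) / rate
  total_s <- total / 1000
  flat <- total_s / 2
  env <- ifelse(t < flat, 1, 0.5 * (1 + cos(pi * (t - flat) / (total_s - flat))))
  digitized_trace(amplitude * cos(2 * pi * f0 * t) * env, rate)
}

#' Burst of white noise
#'
#' @param duration burst length, ms.
#' @param sd noise standard deviation, volts.
#' @param rate sampling rate, Hz.
#' @param seed RNG seed; required for reproducibility, applied locally (the
#'   caller's RNG state is untouched).
#' @return a [digitized_trace()] of zero-mean normal noise with a
#'   rectangular envelope.
#' @export
noise_burst <- function(duration = 25, sd = 1, rate = 44100, seed = NULL) {
  stopifnot(duration >= 0, sd >= 0, rate > 0)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- round(duration / 1000 * rate)
  digitized_trace(stats::rnorm(n, 0, sd), rate)
}

#' Repeat a waveform with random inter-stimulus intervals
#'
#' Places `n` copies of `waveform` with i.i.d. uniform onset-to-onset gaps
#' drawn from `isi_range`, and records the realized (grid-snapped) onsets in
#' a schedule.  This is the bench's presentation loop: repetitions of a
#' sound with random uniform inter-stimulus intervals.
#'
#' @param waveform a [digitized_trace()] to repeat.
#' @param n number of presentations.
#' @param isi_range two-element range of onset-to-onset intervals, seconds.
#' @param seed RNG seed (applied locally).
#' @param label `trial_type` recorded for every event.
#' @param tail silence appended after the last stimulus, seconds.
#' @return `list(trace = <digitized_trace>, schedule = <data.frame>)`, the
#'   schedule having columns `onset` (s), `duration` (s), `trial_type`.
#' @export
stimulus_train <- function(waveform, n, isi_range = c(0.25, 1), seed = NULL,
                           label = "stim", tail = 0.35) {
  stopifnot(inherits(waveform, "digitized_trace"), n >= 0,
            length(isi_range) == 2, isi_range[1] > 0,
            isi_range[2] >= isi_range[1])
  rate <- waveform$rate
  if (n == 0)
    return(list(trace = digitized_trace(numeric(0), rate),
                schedule = data.frame(onset = numeric(0), duration = numeric(0),
                                      trial_type = character(0))))
  if (!is.null(seed)) withr::local_seed(seed)
  gaps <- stats::runif(n, isi_range[1], isi_range[2])
  idx <- round(cumsum(gaps) * rate)        # snap onsets to the playback grid
  onsets <- idx / rate
  wn <- length(waveform$values)
  total <- max(idx) + wn + round(tail * rate)
  values <- numeric(total)
  for (k in seq_len(n)) {
    j <- idx[k] + seq_len(wn)
    values[j] <- values[j] + waveform$values
  }
  list(trace = digitized_trace(values, rate),
       schedule = data.frame(onset = onsets,
                             duration = rep(wn / rate, n),
                             trial_type = rep(label, n)))
}

#' Train of independently generated noise bursts
#'
#' Like [stimulus_train()], but every presentation is a fresh noise burst
#' rather than a copy of one waveform — the pulse-duration bench plays
#' independently generated bursts, so the last supra-threshold sample falls
#' at a different place in every trial.
#'
#' @param n number of bursts.
#' @param duration burst length, ms.
#' @param sd noise standard deviation, volts.
#' @param rate rendering rate, Hz.
#' @param isi_range onset-to-onset interval range, seconds.
#' @param seed RNG seed (applied locally; gaps and all bursts drawn from it).
#' @param tail trailing silence, seconds.
#' @return `list(trace, schedule)` as in [stimulus_train()].
#' @export
noise_burst_train <- function(n, duration = 25, sd = 1, rate = 44100,
                              isi_range = c(0.25, 1), seed = NULL,
                              tail = 0.35) {
  stopifnot(n >= 0, duration > 0, sd >= 0, rate > 0)
  if (n == 0)
    return(list(trace = digitized_trace(numeric(0), rate),
                schedule = data.frame(onset = numeric(0), duration = numeric(0),
                                      trial_type = character(0))))
  if (!is.null(seed)) withr::local_seed(seed)
  gaps <- stats::runif(n, isi_range[1], isi_range[2])
  idx <- round(cumsum(gaps) * rate)
  wn <- round(duration / 1000 * rate)
  values <- numeric(max(idx) + wn + round(tail * rate))
  for (k in seq_len(n))
    values[idx[k] + seq_len(wn)] <- stats::rnorm(wn, 0, sd)
  list(trace = digitized_trace(values, rate),
       schedule = data.frame(onset = idx / rate, duration = rep(wn / rate, n),
                             trial_type = rep("burst", n)))
}

#' Auditory oddball stimulus sequence
#'
#' A randomized sequence of discrete sounds presented on a fixed
#' stimulus-onset-asynchrony grid: frequent "standard" square-wave beeps,
#' rarer "target" beeps at a higher fundamental, and a small minority of
#' "distractor" sounds, each a unique seeded noise-like waveform that occurs
#' only once.
#'
#' @param n_standard,n_target,n_distractor event counts (defaults 270/80/60).
#' @param soa stimulus-onset asynchrony, seconds (events at `0, soa, 2*soa, ...`).
#' @param beep_duration beep length, ms.
#' @param f_standard,f_target square-wave fundamentals, Hz.
#' @param amplitude peak amplitude, volts.
#' @param rate rendering rate, Hz.
#' @param seed RNG seed (applied locally).
#' @param tail silence appended after the last event, seconds.
#' @return `list(trace, schedule)` as in [stimulus_train()], with
#'   `trial_type` in `standard`/`target`/`distractor`.
#' @export
oddball_sequence <- function(n_standard = 270, n_target = 80,
                             n_distractor = 60, soa = 1, beep_duration = 340,
                             f_standard = 400, f_target = 575, amplitude = 1,
                             rate = 44100, seed = NULL, tail = 0.5) {
  stopifnot(n_standard >= 0, n_target >= 0, n_distractor >= 0, soa > 0,
            beep_duration > 0, rate > 2 * max(f_standard, f_target))
  n <- n_standard + n_target + n_distractor
  if (n == 0)
    return(list(trace = digitized_trace(numeric(0), rate),
                schedule = data.frame(onset = numeric(0), duration = numeric(0),
                                      trial_type = character(0))))
  if (!is.null(seed)) withr::local_seed(seed)
  labels <- sample(rep(c("standard", "target", "distractor"),
                       c(n_standard, n_target, n_distractor)))
  onsets <- (seq_len(n) - 1) * soa
  wn <- round(beep_duration / 1000 * rate)
  tw <- (seq_len(wn) - 1) / rate
  square <- function(f) amplitude * sign(sin(2 * pi * f * tw) + .Machine$double.eps)
  std_wave <- square(f_standard)
  tgt_wave <- square(f_target)
  total <- round((n - 1) * soa * rate) + wn + round(tail * rate)
  values <- numeric(total)
  durations <- numeric(n)
  for (k in seq_len(n)) {
    w <- switch(labels[k],
                standard = std_wave,
                target = tgt_wave,
                distractor = {
                  # unique noise-like waveform: AR(1)-colored noise, renormalized
                  x <- stats::filter(stats::rnorm(wn), 0.95, method = "recursive")
                  as.numeric(x) / max(abs(x)) * amplitude
                })
    j <- round(onsets[k] * rate) + seq_len(wn)
    values[j] <- values[j] + w
    durations[k] <- wn / rate
  }
  list(trace = digitized_trace(values, rate),
       schedule = data.frame(onset = onsets, duration = durations,
                             trial_type = labels))
}

#' Virtual digitizer
#'
#' Captures an analog source on a uniform grid, emulating the bench
#' digitizer that records stimulus and TTL lines together (100 kHz by
#' default, i.e. 10 µs time resolution: any edge time observed *through*
#' the capture is quantized to that grid).
#'
#' @param source function of time (s) or [digitized_trace()]; traces are
#'   read through linear interpolation.
#' @param duration capture length, seconds.
#' @param rate digitizer rate, Hz.
#' @param start_time capture start, seconds.
#' @return a [digitized_trace()].
#' @export
digitize <- function(source, duration, rate = 1e5, start_time = 0) {
  stopifnot(rate > 0, duration >= 0)
  f <- analog_source(source)
  n <- round(duration * rate)
  t <- start_time + (seq_len(n) - 1) / rate
  digitized_trace(f(t), rate, start_time)
}
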