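#' Latency / jitter characterization bench
#'
#' End-to-end emulation of the response-timing experiment: repeated
#' abrupt-onset cosine-phase tones with random uniform inter-stimulus
#' intervals are fed to the emulated device (all channels configured as
#' independent triggers reading the same source), the stimulus and the
#' first channel's TTL output are captured by the virtual digitizer, sound
#' onsets are estimated by sample-to-sample change detection plus
#' group correction, TTL onsets by interpolated edge extraction, and the
#' paired input-to-output latencies are summarized.
#'
#' The default refractory period (200 ms) exceeds the 100 ms stimulus
#' envelope, preventing within-stimulus re-triggers, while staying below
#' the 250 ms inter-stimulus floor.
#'
#' @param n_stimuli number of tone presentations.
#' @param n_channels number of trigger channels scanned per tick (1–8).
#' @param sampling_frequency device sampling rate, Hz.
#' @param trigger_cost per-channel processing cost, µs.
#' @param threshold trigger threshold, ADC counts.
#' @param refractory_period trigger refractory period, µs.
#' @param amplitude tone amplitude, volts.
#' @param isi_range inter-stimulus (onset-to-onset) interval range, s.
#' @param tone_rate stimulus playback rate, Hz.
#' @param digitizer_rate virtual digitizer rate, Hz.
#' @param diff_threshold onset-detector sample-to-sample change threshold, V.
#' @param seed RNG seed for the stimulus schedule.
#' @return list with `report` (a [timing_report()]), `input_onsets`,
#'   `output_onsets` (s), `schedule`, `n_detected`, and the device
#'   `idle_fraction`.
#' @export
bench_latency <- function(n_stimuli = 187, n_channels = 8,
                          sampling_frequency = 6250, trigger_cost = 16.5,
                          threshold = 50, refractory_period = 200000,
                          amplitude = 1, isi_range = c(0.25, 1),
                          tone_rate = 44100, digitizer_rate = 1e5,
                          diff_threshold = 0.1, seed = NULL) {
  tone <- onset_tone(f0 = 100, amplitude = amplitude, total = 100,
                     rate = tone_rate)
  st <- stimulus_train(tone, n_stimuli, isi_range = isi_range, seed = seed,
                       label = "tone")
  duration <- trace_duration(st$trace)
  device <- device_config(
    trigger_channels(n_channels, sampling_frequency, threshold = threshold,
                     min_pulse_duration = 10000, pulse_increment = 0,
                     refractory_period = refractory_period),
    trigger_cost = trigger_cost)
  src <- analog_source(st$trace)
  sim <- simulate_device(device, src, sampling_frequency, duration)

  stim_dig <- digitize(src, duration, rate = digitizer_rate)
  ttl_dig <- render_pulse_train(sim$pulse_trains[[1]], digitizer_rate, duration)

  raw_onsets <- detect_onsets(stim_dig, diff_threshold, min_separation = 0.1)
  input_onsets <- as.numeric(group_correct(stim_dig, raw_onsets))
  output_onsets <- pulse_onsets(edge_times(ttl_dig))

  report <- latency_stats(input_onsets, output_onsets, pairing_window = 0.02)
  list(report = report, input_onsets = input_onsets,
       output_onsets = output_onsets, schedule = st$schedule,
       n_detected = length(input_onsets), idle_fraction = sim$idle_fraction,
       sampling_frequency = sampling_frequency, n_channels = n_channels)
}

#' Pulse-duration characterization bench
#'
#' Plays repeated noise bursts into a single emulated trigger channel and
#' measures the output pulse durations — exactly (from the emulator's pulse
#' train) and through the virtual digitizer.  With `pulse_increment = 0`
#' the output has fixed duration (the minimum duration quantized up to the
#' sample period); with a positive increment the pulse rides through gaps
#' in the noise and outlasts the burst by roughly the increment.
#'
#' @param n_bursts number of noise bursts.
#' @param burst_duration burst length, ms.
#' @param noise_ratio noise standard deviation as a multiple of the
#'   threshold voltage.
#' @param min_pulse_duration,pulse_increment trigger durations, µs.
#' @param threshold trigger threshold, ADC counts.
#' @param sampling_frequency device rate, Hz.
#' @param isi_range inter-burst interval range, s.
#' @param audio_rate playback rate of the noise, Hz.
#' @param digitizer_rate virtual digitizer rate, Hz.
#' @param seed RNG seed for the bursts and intervals.
#' @return list with `durations_exact` and `durations_digitized` (s),
#'   their means/sds (ms), `n_pulses`, and `supra_fraction` (fraction of
#'   within-burst device samples above threshold).
#' @export
bench_pulse_duration <- function(n_bursts = 200, burst_duration = 25,
                                 noise_ratio = 4, min_pulse_duration = 10000,
                                 pulse_increment = 0, threshold = 50,
                                 sampling_frequency = 6250,
                                 isi_range = c(0.25, 1), audio_rate = 44100,
                                 digitizer_rate = 1e5, seed = NULL) {
  thr_volts <- threshold / 1024 * 3.3
  st <- noise_burst_train(n_bursts, duration = burst_duration,
                          sd = noise_ratio * thr_volts, rate = audio_rate,
                          isi_range = isi_range, seed = seed)
  duration <- trace_duration(st$trace)
  device <- device_config(
    trigger_channels(1, sampling_frequency, threshold = threshold,
                     min_pulse_duration = min_pulse_duration,
                     pulse_increment = pulse_increment,
                     refractory_period = 200000))
  src <- analog_source(st$trace)
  sim <- simulate_device(device, src, sampling_frequency, duration)
  train <- sim$pulse_trains[[1]]

  ttl_dig <- render_pulse_train(train, digitizer_rate, duration)
  measured <- edge_times(ttl_dig)

  counts <- sim$adc_traces[[1]]
  tt <- trace_times(counts)
  in_burst <- rep(FALSE, length(tt))
  for (on in st$schedule$onset)
    in_burst <- in_burst | (tt >= on & tt < on + burst_duration / 1000)
  supra_fraction <- mean(counts$values[in_burst] > threshold)

  de <- pulse_durations(train); dd <- pulse_durations(measured)
  list(durations_exact = de, durations_digitized = dd,
       mean_exact_ms = mean(de, na.rm = TRUE) * 1000,
       sd_exact_ms = stats::sd(de) * 1000,
       mean_digitized_ms = mean(dd, na.rm = TRUE) * 1000,
       sd_digitized_ms = stats::sd(dd) * 1000,
       n_pulses = n_pulses(train), supra_fraction = supra_fraction,
       schedule = st$schedule)
}

#' Sequential-scan onset offsets between channels
#'
#' Feeds all channels of an n-channel device a common voltage step and
#' reports the onset-time difference between the last and the first
#' channel's output pulses.  With the step crossing threshold just before a
#' tick, every channel detects on the same tick and the difference is the
#' summed processing cost of the intervening channels; with the crossing
#' placed *between* the first and last channel's sampling instants within
#' one tick, the last channel picks the onset up one whole sample earlier
#' and the difference drops by one sample period.
#'
#' @param crossing `"pre_tick"` or `"intra_tick"` placement of the step.
#' @param n_channels number of trigger channels.
#' @param trigger_cost per-channel cost, µs.
#' @param sampling_frequency device rate, Hz.
#' @param threshold trigger threshold, counts.
#' @return list with `diff_us` (last minus first onset, µs), the two onset
#'   times (s), and the step time used.
#' @export
bench_scan_offsets <- function(crossing = c("pre_tick", "intra_tick"),
                               n_channels = 8, trigger_cost = 16.7,
                               sampling_frequency = 6250, threshold = 50) {
  crossing <- match.arg(crossing)
  period <- 1e6 / sampling_frequency
  k <- 10   # an arbitrary interior tick
  t_step_us <- switch(crossing,
    pre_tick = k * period - 5,
    intra_tick = k * period + 0.3 * (n_channels - 1) * trigger_cost)
  t_step <- t_step_us / 1e6
  src <- function(t) ifelse(t >= t_step, 1.0, 0.0)
  device <- device_config(
    trigger_channels(n_channels, sampling_frequency, threshold = threshold,
                     min_pulse_duration = 10000, pulse_increment = 0,
                     refractory_period = 100000),
    trigger_cost = trigger_cost)
  sim <- simulate_device(device, src, sampling_frequency,
                         duration = (k + 200) / sampling_frequency)
  first <- pulse_onsets(sim$pulse_trains[[1]])[1]
  last <- pulse_onsets(sim$pulse_trains[[n_channels]])[1]
  list(diff_us = (last - first) * 1e6, first_onset = first, last_onset = last,
       step_time = t_step, crossing = crossing)
}

#' Jitter-smearing demonstration
#'
#' Contrasts two time-locked averages of the same simulated single-trial
#' ERPs: a *hardware-locked* average (epochs aligned to the true physical
#' stimulus onsets, as a trigger box provides) and a *software-locked*
#' average (epochs aligned to software timestamps that lag the physical
#' onsets by a long, jittery audio latency).  The software-locked average
#' is delayed by the mean latency and its peaks are smeared and attenuated
#' by the jitter.  Peaks are measured after a light moving-average smooth.
#'
#' @param n number of trials.
#' @param latency_offset mean audio latency, ms.
#' @param latency_jitter_sd audio-latency jitter, ms.
#' @param noise_sd single-trial noise, µV.
#' @param template an [make_template()] object.
#' @param mmn_window,p3a_window component search windows (hardware-locked
#'   time), ms.
#' @param smooth_k moving-average length (samples) before peak picking.
#' @param seed RNG seed.
#' @return list with the two `erp_average`s, per-component peak metrics,
#'   `latency_shift_ms` (software minus hardware peak latency, per
#'   component), and `attenuation` (software / hardware peak magnitude).
#' @export
erp_demo <- function(n = 410, latency_offset = 227, latency_jitter_sd = 30.7,
                     noise_sd = 10, template = make_template(),
                     mmn_window = c(100, 250), p3a_window = c(250, 450),
                     smooth_k = 5, seed = NULL) {
  hw <- simulate_epochs(template, n, noise_sd = noise_sd, latency_offset = 0,
                        latency_jitter_sd = 0,
                        seed = if (is.null(seed)) NULL else seed)
  sw <- simulate_epochs(template, n, noise_sd = noise_sd,
                        latency_offset = latency_offset,
                        latency_jitter_sd = latency_jitter_sd,
                        seed = if (is.null(seed)) NULL else seed + 1)
  avg_hw <- smooth_average(average_epochs(hw), smooth_k)
  avg_sw <- smooth_average(average_epochs(sw), smooth_k)
  windows <- list(MMN = mmn_window, P3a = p3a_window)
  polarity <- c(MMN = "negative", P3a = "positive")
  peaks <- list()
  shift <- atten <- numeric(0)
  for (comp in names(windows)) {
    wh <- windows[[comp]]
    ph <- peak_metrics(avg_hw, wh, polarity[[comp]])
    ps <- peak_metrics(avg_sw, wh + latency_offset, polarity[[comp]])
    peaks[[comp]] <- list(hardware = ph, software = ps)
    shift[comp] <- ps$latency - ph$latency
    atten[comp] <- abs(ps$amplitude) / abs(ph$amplitude)
  }
  list(hardware_locked = avg_hw, software_locked = avg_sw, peaks = peaks,
       latency_shift_ms = shift, attenuation = atten,
       latency_offset = latency_offset,
       latency_jitter_sd = latency_jitter_sd, n = n)
}
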