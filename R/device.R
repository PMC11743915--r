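#' Analog front-end of one input channel
#'
#' Models how a channel's physical input reaches the ADC.  A `half_wave`
#' front-end feeds the signal straight to the unipolar converter, so
#' negative excursions are simply not captured (the half-wave-rectifier
#' effect of reading a bipolar audio signal with a 0–Vcc ADC).  A
#' `dc_biased` front-end first shifts the signal up by `Vcc/2` (1.65 V for
#' the default 3.3 V supply) so negative excursions become measurable
#' positive voltages.
#'
#' @param kind `"half_wave"` or `"dc_biased"`.
#' @param full_scale ADC full-scale voltage (the supply voltage), volts.
#' @param adc_bits converter resolution in bits (10 by default).
#' @param bias DC bias in volts; defaults to 0 (`half_wave`) or
#'   `full_scale / 2` (`dc_biased`).
#' @return an object of class `channel_front_end`.
#' @export
channel_front_end <- function(kind = c("half_wave", "dc_biased"),
                              full_scale = 3.3, adc_bits = 10, bias = NULL) {
  kind <- match.arg(kind)
  if (is.null(bias)) bias <- if (kind == "dc_biased") full_scale / 2 else 0
  stopifnot(full_scale > 0, bias >= 0, bias <= full_scale,
            adc_bits >= 1, adc_bits == round(adc_bits))
  structure(list(kind = kind, bias = as.numeric(bias),
                 full_scale = as.numeric(full_scale),
                 adc_bits = as.integer(adc_bits)),
            class = "channel_front_end")
}

#' Read a voltage through a front-end and ADC
#'
#' Applies the front-end bias, clamps to the converter's 0..`full_scale`
#' input range, and quantizes:
#' `counts = min(floor(v_clamped / full_scale * 2^bits), 2^bits - 1)`.
#' Vectorized over `v`; monotone non-decreasing in `v`.
#'
#' @param fe a [channel_front_end()].
#' @param v input voltage(s).
#' @return integer-valued ADC counts.
#' @export
#' @examples
#' front_end_read(channel_front_end("half_wave"), -0.5)   # 0: not captured
#' front_end_read(channel_front_end("dc_biased"), 0)      # 512: mid-scale
front_end_read <- function(fe, v) {
  stopifnot(inherits(fe, "channel_front_end"))
  levels <- 2^fe$adc_bits
  x <- pmin(pmax(v + fe$bias, 0), fe$full_scale)
  pmin(floor(x / fe$full_scale * levels), levels - 1)
}

#' One device channel (front-end + channel config)
#'
#' @param config a [trigger_config()] or [switch_config()].
#' @param front_end a [channel_front_end()].
#' @param line_id output-line label; defaults to a positional id at
#'   [device_config()] time.
#' @export
device_channel <- function(config, front_end = channel_front_end(),
                           line_id = NULL) {
  stopifnot(inherits(config, "trigger_config") || inherits(config, "switch_config"),
            inherits(front_end, "channel_front_end"))
  structure(list(config = config, front_end = front_end, line_id = line_id),
            class = "device_channel")
}

#' Whole-device configuration
#'
#' The device scans its channels strictly sequentially on every sample tick.
#' Each trigger channel costs `trigger_cost` µs of processing per sample and
#' each switch channel `switch_cost` µs; a sampling rate is feasible only
#' while the summed per-tick cost stays strictly below the sample period, so
#' that idle loops remain.  The default costs (16.5 / 0.5 µs) are the
#' assignment consistent with all three observed rate ceilings (6.25 kHz for
#' eight triggers, 10 kHz for six triggers plus one switch, 50 kHz for a
#' single trigger) and with the measured 16–17 µs per-trigger processing
#' time; both are configurable.
#'
#' @param channels list of [device_channel()] objects (1–8: tip and ring of
#'   four TRS jacks).
#' @param trigger_cost,switch_cost per-channel per-sample processing cost, µs.
#' @param rate_menu selectable sampling rates, Hz.  The default divides the
#'   50 kHz base rate by the prescaler chain 1, 2, 4, 5, 8, 10, 16, 20
#'   (50 down to 2.5 kHz) — the menu consistent with every observed ceiling:
#'   6.25 kHz for eight triggers, 10 kHz for six triggers plus a switch,
#'   50 kHz for one trigger.
#' @param loop_overhead fixed per-tick overhead, µs.
#' @return an object of class `device_config`.
#' @seealso [simulate_device()], [max_sampling_rate()], [idle_fraction()]
#' @export
device_config <- function(channels, trigger_cost = 16.5, switch_cost = 0.5,
                          rate_menu = 50000 / c(1, 2, 4, 5, 8, 10, 16, 20),
                          loop_overhead = 0) {
  if (inherits(channels, "device_channel")) channels <- list(channels)
  stopifnot(length(channels) >= 1, length(channels) <= 8,
            all(vapply(channels, inherits, TRUE, "device_channel")),
            trigger_cost > 0, switch_cost > 0, loop_overhead >= 0,
            all(rate_menu > 0))
  for (i in seq_along(channels)) {
    if (is.null(channels[[i]]$line_id))
      channels[[i]]$line_id <- sprintf("ch%d", i)
  }
  structure(list(channels = channels, trigger_cost = as.numeric(trigger_cost),
                 switch_cost = as.numeric(switch_cost),
                 rate_menu = sort(as.numeric(rate_menu), decreasing = TRUE),
                 loop_overhead = as.numeric(loop_overhead)),
            class = "device_config")
}

#' Convenience constructor: n identical trigger channels
#'
#' @param n number of channels (1–8).
#' @param sampling_frequency,... passed to [trigger_config()].
#' @param front_end shared [channel_front_end()].
#' @export
trigger_channels <- function(n, sampling_frequency = 6250, ...,
                             front_end = channel_front_end()) {
  lapply(seq_len(n), function(i)
    device_channel(trigger_config(sampling_frequency, ...), front_end))
}

.channel_costs <- function(device) {
  vapply(device$channels, function(ch)
    if (inherits(ch$config, "trigger_config")) device$trigger_cost
    else device$switch_cost, numeric(1))
}

#' Total per-tick processing cost
#' @param device a [device_config()].
#' @return summed channel costs plus loop overhead, µs.
#' @export
tick_cost <- function(device) {
  stopifnot(inherits(device, "device_config"))
  sum(.channel_costs(device)) + device$loop_overhead
}

#' Maximum feasible sampling rate
#'
#' The largest rate on the device's menu whose sample period strictly
#' exceeds the total per-tick processing cost — i.e. the fastest setting at
#' which idle loops still remain.
#'
#' @param device a [device_config()].
#' @return rate in Hz.
#' @export
#' @examples
#' dev8 <- device_config(trigger_channels(8))
#' max_sampling_rate(dev8)   # 6250
max_sampling_rate <- function(device) {
  stopifnot(inherits(device, "device_config"))
  cost <- tick_cost(device)
  feasible <- cost < 1e6 / device$rate_menu
  if (!any(feasible))
    stop("no feasible rate: per-tick cost ", cost,
         " µs exceeds every menu period")
  max(device$rate_menu[feasible])
}

#' Idle-loop fraction at a given rate
#'
#' Fraction of each sample period left over after all channels are
#' processed: `1 - (sum of channel costs + loop overhead) / period`,
#' floored at 0 (saturated: the firmware can no longer keep up).
#'
#' @param device a [device_config()].
#' @param rate sampling rate, Hz.
#' @return dimensionless value in `[0, 1]`.
#' @export
idle_fraction <- function(device, rate) {
  stopifnot(inherits(device, "device_config"), rate > 0)
  max(0, 1 - tick_cost(device) * rate / 1e6)
}

#' Simulate the whole device on analog sources
#'
#' Emulates one characterization run: tick `n` occurs at `n / rate`; within
#' a tick the channels are processed strictly sequentially, channel `i`
#' sampling the *live* analog source at
#' `n / rate + sum(costs of channels before i)` (there is no
#' sample-and-hold, so channels reading the same source can see different
#' voltages).  A channel's output edges are applied at the instant its
#' processing completes, i.e. its own sample time plus its own cost.
#'
#' @param device a [device_config()].
#' @param sources a single analog source (function of time in seconds, or
#'   [digitized_trace()]) shared by all channels, or a list of one source
#'   per channel.
#' @param sampling_frequency device sampling rate, Hz; must be on the
#'   device's rate menu and feasible.
#' @param duration simulated time, seconds.
#' @return an object of class `device_sim`: list with `pulse_trains` and
#'   `adc_traces` (one per channel), `channel_offsets` (µs within a tick),
#'   `idle_fraction`, and `sampling_frequency`.
#' @export
simulate_device <- function(device, sources, sampling_frequency, duration) {
  stopifnot(inherits(device, "device_config"),
            sampling_frequency > 0, duration > 0)
  if (!any(abs(device$rate_menu - sampling_frequency) <
           1e-6 * sampling_frequency))
    stop("sampling_frequency ", sampling_frequency,
         " Hz is not on the device's rate menu (",
         paste(signif(device$rate_menu, 6), collapse = ", "), ")")
  period <- 1e6 / sampling_frequency
  cost <- tick_cost(device)
  if (cost >= period)
    stop("no idle loops at ", sampling_frequency, " Hz: per-tick cost ",
         cost, " µs >= period ", period,
         " µs; maximum feasible rate is ",
         tryCatch(max_sampling_rate(device), error = function(e) NA),
         " Hz")
  nch <- length(device$channels)
  if (!is.list(sources) || is.function(sources))
    sources <- rep(list(sources), nch)
  stopifnot(length(sources) == nch)
  sources <- lapply(sources, analog_source)

  costs <- .channel_costs(device)
  offsets <- cumsum(c(0, costs))[seq_len(nch)]   # µs before each channel
  n_ticks <- floor(duration * sampling_frequency + 1e-9)
  ticks_us <- (seq_len(n_ticks) - 1) * period

  pulse_trains <- vector("list", nch)
  adc_traces <- vector("list", nch)
  names(pulse_trains) <- names(adc_traces) <-
    vapply(device$channels, function(ch) ch$line_id, character(1))
  for (i in seq_len(nch)) {
    ch <- device$channels[[i]]
    t_us <- ticks_us + offsets[i]
    v <- sources[[i]](t_us / 1e6)
    if (inherits(ch$config, "trigger_config")) {
      counts <- front_end_read(ch$front_end, v)
      thr <- ch$config$threshold
      vv <- counts
      if (ch$config$mode == "dc" && ch$config$polarity == "falling") {
        vv <- -vv; thr <- -thr
      }
      res <- trigger_scan_cpp(vv, offsets[i], period, thr,
                              ch$config$min_pulse_duration,
                              ch$config$pulse_increment,
                              ch$config$refractory_period)
      pulse_trains[[i]] <- pulse_train((res$rise + costs[i]) / 1e6,
                                       (res$fall + costs[i]) / 1e6,
                                       line_id = ch$line_id,
                                       open_end = isTRUE(res$open))
      adc_traces[[i]] <- digitized_trace(counts, sampling_frequency,
                                         start_time = offsets[i] / 1e6,
                                         units = "counts")
    } else {
      closed <- as.numeric(v >= 0.5 * ch$front_end$full_scale)
      tr <- digitized_trace(closed, sampling_frequency,
                            start_time = offsets[i] / 1e6, units = "logic")
      pt <- run_switch(ch$config, tr, line_id = ch$line_id)
      pulse_trains[[i]] <- pulse_train(pt$rise + costs[i] / 1e6,
                                       pt$fall + costs[i] / 1e6,
                                       line_id = ch$line_id,
                                       open_end = pt$open_end)
      adc_traces[[i]] <- tr
    }
  }
  structure(list(pulse_trains = pulse_trains, adc_traces = adc_traces,
                 channel_offsets = offsets,
                 idle_fraction = idle_fraction(device, sampling_frequency),
                 sampling_frequency = sampling_frequency,
                 duration = duration),
            class = "device_sim")
}

#' @export
print.device_sim <- function(x, ...) {
  cat(sprintf("<device_sim> %d channel(s), %g Hz, %.3f s, idle fraction %.3f\n",
              length(x$pulse_trains), x$sampling_frequency, x$duration,
              x$idle_fraction))
  for (nm in names(x$pulse_trains))
    cat(sprintf("  %s: %d pulse(s)\n", nm, n_pulses(x$pulse_trains[[nm]])))
  invisible(x)
}

#' @export
print.device_config <- function(x, ...) {
  kinds <- vapply(x$channels, function(ch)
    if (inherits(ch$config, "trigger_config")) "trigger" else "switch",
    character(1))
  cat(sprintf("<device_config> %d channel(s): %s\n", length(x$channels),
              paste(kinds, collapse = ", ")))
  cat(sprintf("  per-tick cost %.1f µs; max feasible rate %s Hz\n",
              tick_cost(x),
              tryCatch(format(max_sampling_rate(x)), error = function(e) "none")))
  invisible(x)
}
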