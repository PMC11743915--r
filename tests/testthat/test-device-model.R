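test_that("front-end reads: rectification, mid-scale bias, saturation", {
  hw <- channel_front_end("half_wave")
  dc <- channel_front_end("dc_biased")
  expect_equal(front_end_read(hw, -0.5), 0)          # below 0 V: not captured
  expect_equal(front_end_read(dc, 0), 512)           # 1.65 of 3.3 V, 10-bit
  expect_equal(front_end_read(hw, 3.3), 1023)        # clamped full scale
  expect_equal(front_end_read(hw, 10), 1023)
})

test_that("front-end read is monotone and idempotent under clamping", {
  fe <- channel_front_end("dc_biased")
  v <- seq(-3, 5, by = 0.01)
  counts <- front_end_read(fe, v)
  expect_true(all(diff(counts) >= 0))
  expect_equal(front_end_read(fe, pmin(pmax(v, -fe$bias), fe$full_scale - fe$bias)),
               counts)
})

test_that("rate ceilings: 8 triggers, 1 trigger, 6 triggers + 1 switch", {
  expect_equal(max_sampling_rate(device_config(trigger_channels(8))), 6250)
  expect_equal(max_sampling_rate(device_config(trigger_channels(1))), 50000)
  d61 <- device_config(c(trigger_channels(6),
                         list(device_channel(switch_config()))))
  expect_equal(max_sampling_rate(d61), 10000)
  # the 8-trigger and 1-trigger ceilings hold across the whole measured
  # 16-17 µs per-channel cost range
  for (cost in seq(16, 17, by = 0.25)) {
    expect_equal(max_sampling_rate(
      device_config(trigger_channels(8), trigger_cost = cost)), 6250)
    expect_equal(max_sampling_rate(
      device_config(trigger_channels(1), trigger_cost = cost)), 50000)
  }
})

test_that("max rate is non-increasing in channel count and per-channel cost", {
  rates <- vapply(1:8, function(n)
    max_sampling_rate(device_config(trigger_channels(n))), numeric(1))
  expect_true(all(diff(rates) <= 0))
  costs <- c(5, 10, 16, 17, 30)
  by_cost <- vapply(costs, function(cc)
    max_sampling_rate(device_config(trigger_channels(8), trigger_cost = cc)),
    numeric(1))
  expect_true(all(diff(by_cost) <= 0))
})

test_that("idle fraction: formula, saturation, zero-cost limit", {
  d <- device_config(trigger_channels(8), trigger_cost = 16.7)
  expect_equal(idle_fraction(d, 6250), 1 - 133.6 / 160, tolerance = 1e-9)
  expect_equal(idle_fraction(d, 10000), 0)            # 133.6 > 100: saturated
  d_cheap <- device_config(trigger_channels(2), trigger_cost = 1e-9)
  expect_equal(idle_fraction(d_cheap, 6250), 1, tolerance = 1e-6)
})

test_that("infeasible or off-menu rates are rejected with actionable errors", {
  d <- device_config(trigger_channels(8))
  src <- function(t) rep(0, length(t))
  expect_error(simulate_device(d, src, 10000, 0.01), "idle")
  expect_error(simulate_device(d, src, 7000, 0.01), "menu")
})

test_that("sequential scan: +117 µs pre-tick and -43 µs intra-tick channel offsets", {
  pre <- bench_scan_offsets("pre_tick", trigger_cost = 16.7)
  expect_equal(pre$diff_us, 7 * 16.7, tolerance = 1e-6)     # +116.9 µs
  intra <- bench_scan_offsets("intra_tick", trigger_cost = 16.7)
  expect_equal(intra$diff_us, 7 * 16.7 - 160, tolerance = 1e-6)  # -43.1 µs
})

test_that("channel onset differences take only the two lawful values at any phase", {
  withr::local_seed(404)
  period <- 160
  span <- 7 * 16.7
  for (rep in 1:20) {
    t_step_us <- (8 + stats::runif(1)) * period
    src <- local({
      ts <- t_step_us / 1e6
      function(t) ifelse(t >= ts, 1.0, 0.0)
    })
    d <- device_config(trigger_channels(8), trigger_cost = 16.7)
    sim <- simulate_device(d, src, 6250, 0.05)
    diff_us <- (pulse_onsets(sim$pulse_trains[[8]])[1] -
                  pulse_onsets(sim$pulse_trains[[1]])[1]) * 1e6
    expect_true(min(abs(diff_us - span), abs(diff_us - (span - period))) < 1e-6)
  }
})

test_that("a single channel's edges sit one channel cost after its ticks", {
  src <- function(t) ifelse(t >= 0.01, 1.0, 0.0)
  d <- device_config(trigger_channels(1), trigger_cost = 16.5)
  sim <- simulate_device(d, src, 6250, 0.05)
  rise_us <- pulse_onsets(sim$pulse_trains[[1]]) * 1e6
  expect_equal(rise_us %% 160, 16.5, tolerance = 1e-6)
})

test_that("device simulation honours per-channel front-ends and reports idle fraction", {
  src <- function(t) ifelse(t >= 0.01, -0.5, -1)      # negative-only signal
  half <- device_channel(trigger_config(6250, threshold = 50))
  bias <- device_channel(trigger_config(6250, threshold = 300),
                         channel_front_end("dc_biased"))
  d <- device_config(list(half, bias))
  sim <- simulate_device(d, src, 6250, 0.05)
  expect_equal(n_pulses(sim$pulse_trains[[1]]), 0L)   # rectified away
  expect_equal(n_pulses(sim$pulse_trains[[2]]), 1L)   # visible through the bias
  expect_equal(sim$idle_fraction, 1 - 33 / 160, tolerance = 1e-9)
})
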