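test_that("sample-to-sample change detection finds a step at its first new sample", {
  v <- c(rep(0, 5000), rep(1, 5000))
  tr <- digitized_trace(v, 1e4)
  on <- detect_onsets(tr, 0.5)
  expect_equal(length(on), 1L)
  expect_equal(on, 5000 / 1e4)
  expect_equal(length(detect_onsets(digitized_trace(rep(2, 1000), 1e4), 0.5)), 0L)
})

test_that("detections within the dead time are suppressed, later ones kept", {
  v <- numeric(4000)
  v[c(500, 1000, 3000) + 1] <- 1          # impulses 50 ms, then 200 ms apart
  v[c(500, 1000, 3000) + 2] <- 0          # (rate 10 kHz)
  tr <- digitized_trace(v, 1e4)
  expect_equal(length(detect_onsets(tr, 0.5, min_separation = 0.1)), 2L)
  expect_equal(length(detect_onsets(tr, 0.5, min_separation = 0.01)), 3L)
})

test_that("group correction is a fixed point on identical epochs", {
  v <- numeric(5000)
  shape <- sin(seq(0, 2 * pi, length.out = 40))
  ons <- c(1000, 2000, 3000, 4000)
  for (o in ons) v[o + 0:39] <- shape
  tr <- digitized_trace(v, 1000)
  est <- (ons - 1) / 1000
  out <- group_correct(tr, est, window = c(-0.005, 0.045), max_shift = 0.005)
  expect_equal(as.numeric(out), est)
  expect_equal(attr(out, "iterations"), 1L)
})

test_that("group correction recovers injected integer shifts up to a common constant", {
  withr::local_seed(21)
  tmpl <- sin(seq(0, 3 * pi, length.out = 60)) * exp(-(1:60) / 30)
  true_off <- c(-3, 0, 2, 1, -2, 0, 3, -1, 2, -2)
  ons <- 200 + (0:9) * 300
  v <- numeric(3500)
  for (k in seq_along(ons)) v[ons[k] + true_off[k] + 0:59] <- tmpl
  v <- v + rnorm(length(v), 0, 0.02)
  tr <- digitized_trace(v, 1000)
  est <- (ons - 1) / 1000
  out <- group_correct(tr, est, window = c(-0.005, 0.06), max_shift = 0.005)
  rec <- round((as.numeric(out) - est) * 1000)
  expect_equal(rec - rec[2], true_off - true_off[2])
  expect_true(all(diff(attr(out, "mean_correlation")) > -1e-9))
})

test_that("group correction leaves tiny sets unchanged and respects the shift bound", {
  tr <- digitized_trace(rnorm(1000), 1000)
  expect_equal(group_correct(tr, 0.5), 0.5)
  expect_equal(group_correct(tr, numeric(0)), numeric(0))
  withr::local_seed(22)
  v <- rnorm(4000)
  tr2 <- digitized_trace(v, 1000)
  est <- c(0.8, 1.6, 2.4, 3.2)
  out <- group_correct(tr2, est, window = c(-0.01, 0.02), max_shift = 0.003,
                       max_iter = 4)
  expect_true(all(abs(as.numeric(out) - est) <= 4 * 0.003 + 1e-9))
})

test_that("edge extraction interpolates crossings to sub-sample precision", {
  pt <- pulse_train(0.0101234, 0.0101234 + 0.01008)
  tr <- render_pulse_train(pt, 1e5, 0.05)
  got <- edge_times(tr, 1.65)
  expect_equal(n_pulses(got), 1L)
  expect_lt(abs(pulse_durations(got) - 0.01008), 1e-5 + 1e-9)
  expect_lt(abs(pulse_onsets(got) - 0.0101234), 5e-6 + 1e-9)
  # a genuinely analog ramp: crossing recovered between samples
  ramp <- digitized_trace(c(0, 0, 1, 3.3, 3.3, 3.3, 1, 0), 1000)
  e <- edge_times(ramp, 1.65)
  expect_equal(pulse_onsets(e), 0.002 + (0.65 / 2.3) / 1000, tolerance = 1e-9)
})

test_that("edge extraction: empty, all-low, and unterminated cases", {
  expect_equal(n_pulses(edge_times(digitized_trace(rep(0, 100), 1e4))), 0L)
  open_tr <- digitized_trace(c(rep(0, 50), rep(3.3, 50)), 1e4)
  e <- edge_times(open_tr, 1.65)
  expect_equal(n_pulses(e), 1L)
  expect_true(e$open_end)
  expect_true(is.na(pulse_durations(e)))
})

test_that("latency statistics: identity pairing, shift invariance, unpaired counting", {
  on <- c(0.5, 1.2, 2.0)
  r <- latency_stats(on, on, pairing_window = 0.01)
  expect_equal(r$mean, 0); expect_equal(r$sd, 0); expect_equal(r$n, 3L)
  r1 <- latency_stats(on, on + 0.002)
  r2 <- latency_stats(on + 5, on + 5.002)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(r1$mean, 2000)
  # one output missing: that input stays unpaired, the rest still pair
  r3 <- latency_stats(on, on[-2] + 0.001, pairing_window = 0.01)
  expect_equal(r3$n, 2L)
  expect_equal(r3$n_unpaired, 1L)
  expect_error(latency_stats(0.5, 10, pairing_window = 0.01), "no input/output pairs")
})

test_that("timing report enforces its own invariants", {
  r <- timing_report(c(100, 150, 200))
  expect_true(r$min <= r$mean && r$mean <= r$max)
  expect_gte(r$sd, 0)
  expect_error(timing_report(numeric(0)), "no paired")
})

test_that("noiseless pipeline: latency spread stays within one period plus digitizer slack", {
  b <- bench_latency(n_stimuli = 30, n_channels = 1, sampling_frequency = 6250,
                     seed = 33)
  expect_equal(b$report$n, 30L)
  spread <- b$report$max - b$report$min
  expect_lte(spread, 160 + 2 * 10 + 1e-6)
})
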