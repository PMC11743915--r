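test_that("hand-enumerated tick table: onset, fixed duration, refractory suppression", {
  # 1 kHz, threshold 100, min 2 ms, increment 0, refractory 5 ms
  cfg <- trigger_config(1000, threshold = 100, min_pulse_duration = 2000,
                        pulse_increment = 0, refractory_period = 5000)
  tr <- digitized_trace(c(0, 200, 0, 0, 0, 200, 0, 0, 0, 0), 1000)
  pt <- run_trigger(cfg, tr)
  expect_equal(n_pulses(pt), 1L)
  expect_equal(pulse_onsets(pt), 0.001)          # crossing at the 2nd tick
  expect_equal(pulse_durations(pt), 0.002)       # exactly the configured 2 ms
  # the crossing at t = 5 ms is silently suppressed (5 - 1 < 5 ms refractory)
})

test_that("sustained supra-threshold input gives the sample-period-quantized duration", {
  cfg <- trigger_config(6250, threshold = 50, min_pulse_duration = 10000,
                        pulse_increment = 0, refractory_period = 1e6)
  pt <- run_trigger(cfg, digitized_trace(rep(600, 400), 6250))
  expect_equal(n_pulses(pt), 1L)
  expect_equal(pulse_durations(pt) * 1e6, 160 * ceiling(10000 / 160))  # 10080 µs
})

test_that("duration quantization law holds over a parameter sweep", {
  for (fs in c(1000, 6250, 12000)) {
    dt <- 1e6 / fs
    for (min_ms in c(0.5, 2, 7.3, 10)) {
      cfg <- trigger_config(fs, threshold = 50,
                            min_pulse_duration = min_ms * 1000,
                            pulse_increment = 0, refractory_period = 1e6)
      pt <- run_trigger(cfg, digitized_trace(rep(600, 400), fs))
      expect_equal(pulse_durations(pt) * 1e6, dt * ceiling(min_ms * 1000 / dt),
                   tolerance = 1e-9)
    }
  }
  # min = 0, increment = 0: smallest representable pulse (one sample period)
  cfg0 <- trigger_config(6250, 50, 0, 0, 1e6)
  pt0 <- run_trigger(cfg0, digitized_trace(rep(600, 50), 6250))
  expect_equal(pulse_durations(pt0) * 1e6, 160)
})

test_that("sub-threshold input never fires and empty traces give empty trains", {
  cfg <- trigger_config(1000, threshold = 100)
  expect_equal(n_pulses(run_trigger(cfg, digitized_trace(rep(0, 500), 1000))), 0L)
  expect_equal(n_pulses(run_trigger(cfg, digitized_trace(rep(100, 500), 1000))),
               0L)  # strict comparison: equal to threshold is not supra
  expect_equal(n_pulses(run_trigger(cfg, digitized_trace(numeric(0), 1000))), 0L)
})

test_that("two beeps 1 s apart pass an 800 ms refractory as exactly two pulses", {
  fs <- 1000
  v <- numeric(2500)
  for (on in c(100, 1100)) v[on + 1:340] <- 600   # two 340 ms supra beeps
  cfg <- trigger_config(fs, threshold = 50, min_pulse_duration = 10000,
                        pulse_increment = 10000, refractory_period = 8e5)
  pt <- run_trigger(cfg, digitized_trace(v, fs))
  expect_equal(n_pulses(pt), 2L)
  expect_equal(diff(pulse_onsets(pt)), 1, tolerance = 1e-9)
})

test_that("compiled scan matches the naive oracle and the exported step fold", {
  withr::local_seed(101)
  for (rep in 1:40) {
    case <- random_trigger_case()
    got <- run_trigger(case$config, case$trace)
    ref <- oracle_trigger(case$trace$values, trace_times(case$trace) * 1e6,
                          case$config$threshold, case$config$min_pulse_duration,
                          case$config$pulse_increment,
                          case$config$refractory_period)
    expect_edges_equal(got, ref)
    stepped <- fold_trigger_steps(case$config, case$trace)
    expect_edges_equal(got, stepped)
  }
})

test_that("refractory and minimum-duration invariants hold on random inputs", {
  withr::local_seed(202)
  for (rep in 1:60) {
    case <- random_trigger_case()
    pt <- run_trigger(case$config, case$trace)
    if (n_pulses(pt) >= 2)
      expect_true(all(diff(pulse_onsets(pt)) * 1e6 >=
                        case$config$refractory_period - 1e-6))
    d <- pulse_durations(pt) * 1e6
    d <- d[!is.na(d)]
    if (length(d)) {
      dt <- 1e6 / case$config$sampling_frequency
      floor_dur <- max(dt, dt * ceiling(case$config$min_pulse_duration / dt))
      expect_true(all(d >= floor_dur - 1e-6))
    }
  }
})

test_that("trigger_step rejects non-monotone time", {
  cfg <- trigger_config(1000)
  st <- new_trigger_state()
  st <- trigger_step(cfg, st, 0, 1000)$state
  expect_error(trigger_step(cfg, st, 0, 1000), "strictly increasing")
  expect_error(trigger_step(cfg, st, 0, 500), "strictly increasing")
})

test_that("detection latency for uniform-phase onsets is uniform over one period", {
  withr::local_seed(303)
  fs <- 6250
  dt_us <- 1e6 / fs
  n_rep <- 500
  lat <- numeric(n_rep)
  cfg <- trigger_config(fs, threshold = 50, min_pulse_duration = 1000,
                        pulse_increment = 0, refractory_period = 1e5)
  for (k in seq_len(n_rep)) {
    t_step <- (5 + stats::runif(1)) * dt_us          # random phase in tick 5
    tick_t <- (0:39) * dt_us
    v <- ifelse(tick_t >= t_step, 600, 0)
    pt <- run_trigger(cfg, digitized_trace(v, fs))
    lat[k] <- pulse_onsets(pt)[1] * 1e6 - t_step
  }
  expect_true(all(lat >= 0 & lat < dt_us + 1e-6))
  # S.D. converges to dt/sqrt(12); 10% covers >3 sigma of the estimator at n=500
  expect_equal(sd(lat), dt_us / sqrt(12), tolerance = 0.10)
})

test_that("switch de-bouncing: bounces collapse to one event at the stable run start", {
  # 3 bounce transitions inside 2 ms, then a stable closure; debounce 5 ms
  v <- c(rep(0, 10), 1, 0, 1, 0, rep(1, 10), rep(0, 20))
  pt <- run_switch(switch_config(debounce_time = 5000), digitized_trace(v, 1000))
  expect_equal(n_pulses(pt), 1L)
  expect_equal(pulse_onsets(pt), 0.014)   # first closure of the stable run
})

test_that("switch: no closure means no events; 1 Hz press train gives one event per press", {
  cfg <- switch_config(debounce_time = 20000, refractory_period = 1e5)
  expect_equal(n_pulses(run_switch(cfg, digitized_trace(rep(0, 1000), 1000))), 0L)
  v <- numeric(5500)
  for (on in (0:4) * 1000 + 200) v[on + 1:100] <- 1   # 100 ms presses at 1 Hz
  pt <- run_switch(cfg, digitized_trace(v, 1000))
  expect_equal(n_pulses(pt), 5L)
  expect_equal(diff(pulse_onsets(pt)), rep(1, 4), tolerance = 1e-9)
})

test_that("pulse trains validate ordering and expose durations and edges", {
  pt <- pulse_train(c(0.1, 0.5), c(0.2, 0.6), line_id = "d0")
  expect_equal(pulse_durations(pt), c(0.1, 0.1))
  e <- pulse_edges(pt)
  expect_equal(e$level, c("high", "low", "high", "low"))
  expect_true(all(diff(e$time) > 0))
  expect_error(pulse_train(c(0.5, 0.1), c(0.6, 0.2)))
  expect_error(pulse_train(0.1, 0.05))
})
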