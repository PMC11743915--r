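# Naive reference implementation of the trigger rules, written directly from
# their prose statement and kept independent of the package's compiled scan.
# Works on explicit per-sample timestamps; all times in µs.
oracle_trigger <- function(samples, t_us, threshold, min_us, inc_us, refr_us) {
  eps <- 1e-6
  rise <- numeric(0); fall <- numeric(0)
  in_pulse <- FALSE
  onset_t <- NA_real_; supra_t <- NA_real_; start_t <- NA_real_
  for (i in seq_along(samples)) {
    t <- t_us[i]
    sup <- samples[i] > threshold
    if (in_pulse) {
      if (sup) supra_t <- t
      min_ok <- (t - start_t) >= (min_us - eps)
      inc_ok <- (t - supra_t) >= (inc_us - eps)
      if (min_ok && inc_ok) {
        fall <- c(fall, t)
        in_pulse <- FALSE
      }
    } else if (sup) {
      if (is.na(onset_t) || (t - onset_t) >= (refr_us - eps)) {
        rise <- c(rise, t)
        start_t <- t; supra_t <- t; onset_t <- t
        in_pulse <- TRUE
      }
    }
  }
  list(rise = rise, fall = fall, open = in_pulse)
}

# Fold the exported single-step state machine over a trace (second
# independent route to the same edges).
fold_trigger_steps <- function(config, trace) {
  st <- new_trigger_state()
  dt_us <- 1e6 / trace$rate
  t0_us <- trace$start_time * 1e6
  rise <- numeric(0); fall <- numeric(0)
  for (i in seq_along(trace$values)) {
    t <- t0_us + (i - 1) * dt_us
    r <- trigger_step(config, st, trace$values[i], t)
    st <- r$state
    if (identical(r$output, "high")) rise <- c(rise, t)
    if (identical(r$output, "low")) fall <- c(fall, t)
  }
  list(rise = rise, fall = fall, open = identical(st$phase, "in_pulse"))
}

random_trigger_case <- function() {
  fs <- sample(c(1000, 2000, 5000, 6250, 10000), 1)
  dt_us <- 1e6 / fs
  n <- sample(50:200, 1)
  cfg <- trigger_config(
    fs,
    threshold = sample(20:400, 1),
    min_pulse_duration = stats::runif(1, 0, 8) * dt_us,
    pulse_increment = stats::runif(1, 0, 4) * dt_us,
    refractory_period = stats::runif(1, 0, 12) * dt_us)
  values <- sample(0:700, n, replace = TRUE)
  # runs of silence make multi-pulse structure likely
  gaps <- sort(sample(n, min(n, 20)))
  values[gaps] <- 0
  list(config = cfg, trace = digitized_trace(values, fs))
}

expect_edges_equal <- function(train, ref, tol = 1e-9) {
  expect_equal(train$rise * 1e6, ref$rise, tolerance = tol)
  ref_fall <- ref$fall
  got_fall <- train$fall * 1e6
  if (train$open_end) got_fall <- got_fall[-length(got_fall)]
  expect_equal(got_fall, ref_fall, tolerance = tol)
  expect_identical(train$open_end, isTRUE(ref$open))
}
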