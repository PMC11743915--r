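#' Default ERP difference-wave components
#'
#' Demonstration components for a distractor-minus-standard auditory
#' difference wave: a mismatch-negativity-like negative peak inside the
#' 100–250 ms window and a P3a-like positive peak near 300 ms.  Amplitudes
#' and widths are illustrative defaults, not measured values.
#'
#' @param amplitudes peak amplitudes, µV (signed).
#' @param latencies peak latencies, ms post-stimulus.
#' @param widths Gaussian widths (standard deviations), ms.
#' @param labels component names.
#' @return data frame with one row per component.
#' @export
erp_components <- function(amplitudes = c(-3, 5), latencies = c(175, 300),
                           widths = c(40, 60), labels = c("MMN", "P3a")) {
  stopifnot(length(amplitudes) == length(latencies),
            length(latencies) == length(widths), all(widths > 0))
  data.frame(label = labels, amplitude = amplitudes, latency = latencies,
             width = widths)
}

#' Build an ERP template waveform
#'
#' Sums scaled Gaussian bumps, one per component, on a uniform time grid.
#' Because the components are closed-form, the template can also be
#' evaluated at arbitrary (shifted) times, which [simulate_epochs()] uses to
#' apply continuous latency shifts exactly.
#'
#' All ERP-module times are in milliseconds and amplitudes in microvolts.
#'
#' @param components a data frame as from [erp_components()].
#' @param rate sampling rate of the grid, Hz (300 by default).
#' @param span time range `c(from, to)` relative to stimulus onset, ms.
#' @return object of class `erp_template`: list with `time` (ms), `values`
#'   (µV), `fun` (vectorized closed form), `components`, `rate`.
#' @export
make_template <- function(components = erp_components(), rate = 300,
                          span = c(-100, 700)) {
  stopifnot(is.data.frame(components), rate > 0, span[1] < span[2])
  fun <- function(t_ms) {
    out <- numeric(length(t_ms))
    for (i in seq_len(nrow(components)))
      out <- out + components$amplitude[i] *
        exp(-(t_ms - components$latency[i])^2 / (2 * components$width[i]^2))
    out
  }
  dt <- 1000 / rate
  time <- seq(span[1], span[2], by = dt)
  structure(list(time = time, values = fun(time), fun = fun,
                 components = components, rate = rate),
            class = "erp_template")
}

#' @export
print.erp_template <- function(x, ...) {
  cat(sprintf("<erp_template> %d component(s) on [%g, %g] ms @ %g Hz\n",
              nrow(x$components), min(x$time), max(x$time), x$rate))
  print(x$components)
  invisible(x)
}

#' Simulate single-trial epochs with latency jitter
#'
#' Each epoch is the template shifted in time by
#' `latency_offset + N(0, latency_jitter_sd)` plus i.i.d. additive noise —
#' the situation of a stimulus-presentation chain whose true audio onsets
#' lag the software timestamps by a jittery latency.  The true shifts are
#' retained for oracle tests.
#'
#' @param template an [make_template()] object.
#' @param n number of epochs.
#' @param noise_sd additive noise standard deviation, µV.
#' @param latency_offset mean latency shift, ms.
#' @param latency_jitter_sd trial-to-trial latency jitter, ms.
#' @param seed RNG seed (applied locally).
#' @return object of class `epoch_set`: list with `epochs` (n x time
#'   matrix), `time` (ms), `shifts` (ms, the true per-trial latencies).
#' @export
simulate_epochs <- function(template, n, noise_sd = 10, latency_offset = 0,
                            latency_jitter_sd = 0, seed = NULL) {
  stopifnot(inherits(template, "erp_template"), n >= 1, noise_sd >= 0,
            latency_jitter_sd >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  shifts <- latency_offset + stats::rnorm(n, 0, latency_jitter_sd)
  tt <- template$time
  epochs <- t(vapply(shifts, function(s) template$fun(tt - s),
                     numeric(length(tt))))
  if (noise_sd > 0)
    epochs <- epochs + matrix(stats::rnorm(length(epochs), 0, noise_sd),
                              nrow = n)
  structure(list(epochs = epochs, time = tt, shifts = shifts),
            class = "epoch_set")
}

#' Time-locked average with standard error
#'
#' @param epochs an `epoch_set` from [simulate_epochs()] (or any list with
#'   an `epochs` matrix and `time` vector).
#' @return object of class `erp_average`: list with `time` (ms), `mean`,
#'   `se` (µV; `NA` when n < 2), `n`.
#' @export
average_epochs <- function(epochs) {
  e <- epochs$epochs
  if (is.null(e) || nrow(e) == 0) stop("average_epochs: no epochs")
  n <- nrow(e)
  m <- colMeans(e)
  se <- if (n >= 2) apply(e, 2, stats::sd) / sqrt(n) else rep(NA_real_, ncol(e))
  structure(list(time = epochs$time, mean = m, se = se, n = n),
            class = "erp_average")
}

#' Exact expected jittered average (convolution oracle)
#'
#' The expectation of a time-locked average under latency jitter is the
#' template convolved with the latency density.  Computed by numerical
#' quadrature on a fine shift grid, independently of any Monte-Carlo
#' simulation, so it can serve as the oracle for [simulate_epochs()] +
#' [average_epochs()].
#'
#' @param template an [make_template()] object.
#' @param density latency density: a function of shift (ms) integrating
#'   to 1, e.g. `function(s) dnorm(s, 227, 30.7)`.
#' @param support shift range covering effectively all of the density's
#'   mass, ms.
#' @param step quadrature step, ms.
#' @return list with `time` (ms) and `values` (µV) on the template grid.
#' @export
smear_oracle <- function(template, density, support = c(-200, 200),
                         step = 0.25) {
  stopifnot(inherits(template, "erp_template"), is.function(density),
            support[1] < support[2], step > 0)
  s <- seq(support[1], support[2], by = step)
  w <- density(s) * step
  tot <- sum(w)
  if (abs(tot - 1) > 0.01)
    stop("smear_oracle: density mass over the support is ", signif(tot, 4),
         "; widen `support` or check the density")
  w <- w / tot
  vals <- outer(template$time, s, function(t, sh) template$fun(t - sh)) %*% w
  list(time = template$time, values = as.numeric(vals))
}

#' Peak amplitude and latency within a window
#'
#' Polarity-aware extremum search: the most negative value for
#' `"negative"`, most positive for `"positive"`, largest magnitude for
#' `"absolute"`.  A flat waveform reports amplitude 0 at the window start
#' (first-sample tie rule; ties generally resolve to the earliest sample).
#'
#' @param waveform anything with `time` and `values` fields (an
#'   [make_template()] output, a [smear_oracle()] result) or an
#'   `erp_average` (its `mean` is used).
#' @param window search window `c(from, to)`, ms; must intersect the grid.
#' @param polarity `"negative"`, `"positive"` or `"absolute"`.
#' @return `list(amplitude = µV, latency = ms)`.
#' @export
peak_metrics <- function(waveform, window,
                         polarity = c("negative", "positive", "absolute")) {
  polarity <- match.arg(polarity)
  vals <- if (inherits(waveform, "erp_average")) waveform$mean else waveform$values
  tt <- waveform$time
  stopifnot(length(window) == 2, window[1] <= window[2])
  in_win <- tt >= window[1] & tt <= window[2]
  if (!any(in_win)) stop("peak_metrics: window contains no samples")
  v <- vals[in_win]; t <- tt[in_win]
  i <- switch(polarity,
              negative = which.min(v),
              positive = which.max(v),
              absolute = which.max(abs(v)))
  list(amplitude = v[i], latency = t[i])
}

#' Moving-average smooth of an ERP average
#'
#' Boxcar smoothing before peak picking, the usual guard against
#' single-sample noise peaks.  `k` is forced odd; endpoints use the
#' shrinking window.
#'
#' @param avg an `erp_average` (or list with `time` / `mean`).
#' @param k window length in samples.
#' @return the input with `mean` smoothed (and `values` set for
#'   convenience).
#' @export
smooth_average <- function(avg, k = 5) {
  if (k < 2) return(avg)
  if (k %% 2 == 0) k <- k + 1
  m <- if (inherits(avg, "erp_average")) avg$mean else avg$values
  sm <- stats::filter(m, rep(1 / k, k), sides = 2)
  half <- (k - 1) / 2
  n <- length(m)
  for (i in seq_len(half)) {
    sm[i] <- mean(m[1:(i + half)])
    sm[n - i + 1] <- mean(m[(n - i + 1 - half):n])
  }
  avg$mean <- as.numeric(sm)
  avg$values <- avg$mean
  avg
}
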