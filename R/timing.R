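#' Detect abrupt onsets by sample-to-sample change
#'
#' Flags the first sample at which the absolute sample-to-sample change in
#' voltage exceeds `diff_threshold`; further detections within
#' `min_separation` of an accepted onset are suppressed, so one event yields
#' one onset.
#'
#' @param trace a [digitized_trace()] (volts).
#' @param diff_threshold threshold on `|v[i+1] - v[i]|`, volts.
#' @param min_separation dead time after each accepted onset, seconds.  The
#'   default (100 ms) sits between the longest stimulus envelope feature and
#'   the shortest inter-stimulus interval of the bench.
#' @return numeric vector of onset times (s); possibly empty.
#' @export
detect_onsets <- function(trace, diff_threshold, min_separation = 0.1) {
  stopifnot(inherits(trace, "digitized_trace"), diff_threshold > 0,
            min_separation >= 0)
  v <- trace$values
  if (length(v) < 2L) return(numeric(0))
  hit <- which(abs(diff(v)) > diff_threshold) + 1L   # first sample of new level
  if (!length(hit)) return(numeric(0))
  t <- trace$start_time + (hit - 1L) / trace$rate
  keep <- numeric(0)
  i <- 1L
  n <- length(t)
  while (i <= n) {
    keep <- c(keep, t[i])
    # jump past the dead time (binary search keeps this O(events * log n))
    i <- i + findInterval(t[i] + min_separation, t[i:n])
  }
  keep
}

#' Group-correct onset estimates by realignment to the mean epoch
#'
#' Woody-style iterative realignment: cut a time-locked epoch around each
#' onset estimate, compute the mean epoch, shift each estimate (within
#' `± max_shift`) to the lag at which its epoch correlates best with the
#' mean, and repeat until no estimate moves or `max_iter` sweeps have run.
#' This stops onset estimates from being unduly influenced by small random
#' peri-threshold differences in sample voltage.  Correlation ties are
#' broken toward the smallest shift magnitude (preferring the original
#' estimate); the full mean epoch (not leave-one-out) is used.
#'
#' @param trace the recording the onsets index into.
#' @param onsets onset estimates, seconds.
#' @param window epoch window around each onset, `c(pre, post)` seconds
#'   (pre is negative).
#' @param max_shift maximum per-sweep shift of one estimate, seconds.
#' @param max_iter maximum number of realignment sweeps.
#' @return corrected onset times (s), with attribute `"iterations"` (sweeps
#'   used) and `"mean_correlation"` (per-sweep mean epoch-to-template
#'   correlation).  Fewer than two onsets are returned unchanged.
#' @export
group_correct <- function(trace, onsets, window = c(-0.001, 0.005),
                          max_shift = 0.002, max_iter = 10) {
  stopifnot(inherits(trace, "digitized_trace"), max_shift > 0, max_iter >= 1,
            length(window) == 2, window[1] < window[2])
  if (length(onsets) < 2L) return(onsets)
  v <- trace$values
  rate <- trace$rate
  pre <- round(window[1] * rate); post <- round(window[2] * rate)
  L <- max(1L, round(max_shift * rate))
  win <- pre:post
  o <- round((onsets - trace$start_time) * rate) + 1L
  # estimates whose epoch (with shift margin) fits inside the trace take part
  ok <- (o + pre - L) >= 1L & (o + post + L) <= length(v)
  lags <- -L:L
  lag_order <- order(abs(lags), lags)
  corr_hist <- numeric(0)
  iters <- 0L
  for (iter in seq_len(max_iter)) {
    iters <- iter
    m <- colMeans(do.call(rbind, lapply(o[ok], function(oi) v[oi + win])))
    moved <- FALSE
    rr <- numeric(0)
    for (k in which(ok)) {
      seg <- v[o[k] + rep(win, length(lags)) +
                 rep(lags, each = length(win))]
      segs <- matrix(seg, nrow = length(win))
      r <- suppressWarnings(as.numeric(stats::cor(m, segs)))
      r[is.na(r)] <- -Inf
      if (all(!is.finite(r))) next
      best <- lag_order[which.max(r[lag_order] >= max(r) - 1e-12)]
      l_star <- lags[best]
      rr <- c(rr, max(r))
      if (l_star != 0L) { o[k] <- o[k] + l_star; moved <- TRUE }
    }
    corr_hist <- c(corr_hist, mean(rr))
    if (!moved) break
  }
  out <- trace$start_time + (o - 1L) / rate
  attr(out, "iterations") <- iters
  attr(out, "mean_correlation") <- corr_hist
  out
}

#' Extract TTL edges from a digitized pulse recording
#'
#' Finds rising and falling crossings of `logic_threshold` in a captured
#' TTL trace.  Edge times are interpolated linearly between the two samples
#' bracketing each crossing, giving sub-sample precision; pulse durations
#' follow as fall minus rise.  A final pulse that never falls is reported
#' with `open_end = TRUE`.
#'
#' @param ttl a [digitized_trace()] of the recorded logic line (volts).
#' @param logic_threshold decision level, volts; defaults to 50% of the
#'   observed high level.
#' @param line_id label for the resulting train.
#' @return a [pulse_train()].
#' @export
edge_times <- function(ttl, logic_threshold = NULL, line_id = "ttl") {
  stopifnot(inherits(ttl, "digitized_trace"))
  v <- ttl$values
  if (!length(v)) return(pulse_train(numeric(0), numeric(0), line_id = line_id))
  if (is.null(logic_threshold)) logic_threshold <- 0.5 * max(v)
  if (logic_threshold <= min(v) || logic_threshold >= max(v))
    return(pulse_train(numeric(0), numeric(0), line_id = line_id))
  above <- v > logic_threshold
  t <- trace_times(ttl)
  ix <- which(above[-1L] != above[-length(above)])   # crossing in (ix, ix+1)
  frac <- (logic_threshold - v[ix]) / (v[ix + 1L] - v[ix])
  tc <- t[ix] + frac / ttl$rate
  rising <- !above[ix]
  rise <- tc[rising]; fall <- tc[!rising]
  if (above[1L]) rise <- c(t[1L], rise)   # pulse already high at capture start
  open <- length(rise) == length(fall) + 1L
  pulse_train(rise, fall, line_id = line_id, open_end = open)
}

#' Latency / jitter report
#'
#' Summary statistics over a set of paired latencies, in microseconds.
#'
#' @param latencies_us numeric vector of latencies, µs.
#' @param n_unpaired how many candidate events could not be paired.
#' @return object of class `timing_report` with fields `n`, `mean`, `sd`,
#'   `min`, `max` (µs) and `n_unpaired`.
#' @export
timing_report <- function(latencies_us, n_unpaired = 0) {
  n <- length(latencies_us)
  if (n == 0) stop("timing_report: no paired latencies")
  structure(list(n = n, mean = mean(latencies_us),
                 sd = if (n > 1) stats::sd(latencies_us) else NA_real_,
                 min = min(latencies_us), max = max(latencies_us),
                 n_unpaired = n_unpaired),
            class = "timing_report")
}

#' @export
print.timing_report <- function(x, ...) {
  cat(sprintf(
    "<timing_report> latency %.1f µs ±%.1f S.D. (min = %.0f, max = %.0f, n = %d%s)\n",
    x$mean, x$sd, x$min, x$max, x$n,
    if (x$n_unpaired > 0) sprintf(", %d unpaired", x$n_unpaired) else ""))
  invisible(x)
}

#' @export
as.data.frame.timing_report <- function(x, ...) {
  data.frame(n = x$n, mean_us = x$mean, sd_us = x$sd, min_us = x$min,
             max_us = x$max, n_unpaired = x$n_unpaired)
}

#' Input-to-output latency statistics
#'
#' Pairs each input onset with the nearest *following* output onset no more
#' than `pairing_window` later; each output is consumed by at most one
#' input, unpaired events on either side are counted and excluded, and the
#' report summarizes the paired differences in microseconds.
#'
#' @param input_onsets,output_onsets onset times, seconds.
#' @param pairing_window maximum accepted latency, seconds.
#' @return a [timing_report()].
#' @export
latency_stats <- function(input_onsets, output_onsets, pairing_window = 0.02) {
  stopifnot(pairing_window > 0)
  input_onsets <- sort(input_onsets); output_onsets <- sort(output_onsets)
  lat <- numeric(0)
  unpaired <- 0L
  j <- 1L
  for (ti in input_onsets) {
    while (j <= length(output_onsets) && output_onsets[j] < ti) j <- j + 1L
    if (j <= length(output_onsets) && output_onsets[j] <= ti + pairing_window) {
      lat <- c(lat, (output_onsets[j] - ti) * 1e6)
      j <- j + 1L
    } else {
      unpaired <- unpaired + 1L
    }
  }
  if (!length(lat)) stop("latency_stats: no input/output pairs within window")
  timing_report(lat, n_unpaired = unpaired)
}
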