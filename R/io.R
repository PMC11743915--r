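#' Read a recorded trace from WAV or CSV
#'
#' CSV files must have a header and at least `time` (seconds) and one value
#' column (volts); timestamps must be uniform — the first row breaking
#' uniformity is named in the error.  WAV files (mono PCM16 or IEEE
#' float32) carry their rate in the header; PCM samples are scaled to
#' `[-scale, scale]` volts.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"wav"` or `"csv"`.
#' @param scale full-scale voltage for 16-bit PCM WAV data.
#' @return a [digitized_trace()].
#' @export
read_trace <- function(path, format = c("auto", "wav", "csv"), scale = 1) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  if (!file.exists(path)) stop("read_trace: no such file: ", path)
  if (format == "wav") return(read_wav(path, scale = scale))
  df <- utils::read.csv(path)
  if (!"time" %in% names(df) || ncol(df) < 2)
    stop("read_trace: CSV must have a 'time' column and a value column: ", path)
  vcol <- setdiff(names(df), "time")[1]
  t <- df$time
  if (length(t) < 2) stop("read_trace: need at least two samples: ", path)
  dt <- diff(t)
  bad <- which(abs(dt - dt[1]) > pmax(1e-9, 1e-6 * dt[1]))
  if (length(bad))
    stop("read_trace: non-uniform sampling in ", path, " at row ",
         bad[1] + 2L, " (interval ", signif(dt[bad[1]], 6), " s vs ",
         signif(dt[1], 6), " s)")
  digitized_trace(df[[vcol]], rate = 1 / dt[1], start_time = t[1])
}

#' Write a trace to WAV or CSV
#'
#' @param trace a [digitized_trace()].
#' @param path destination; extension selects the format under `"auto"`.
#' @param format `"auto"`, `"wav"` or `"csv"`.
#' @param wav_format sample encoding for WAV output: IEEE `"float32"` or
#'   `"pcm16"`.
#' @param scale full-scale voltage used when encoding PCM16.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("auto", "wav", "csv"),
                        wav_format = c("float32", "pcm16"), scale = 1) {
  stopifnot(inherits(trace, "digitized_trace"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.wav$", path, ignore.case = TRUE)) "wav" else "csv"
  if (format == "wav") {
    write_wav(trace, path, encoding = match.arg(wav_format), scale = scale)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("time,voltage", con)
    writeLines(sprintf("%.17g,%.17g", trace_times(trace), trace$values), con)
  }
  invisible(path)
}

# --- minimal RIFF/WAVE codec (mono; PCM16 and IEEE float32) ------------------
# No WAV support exists in the installed R stack, so the container format is
# decoded/encoded directly.

read_wav <- function(path, scale = 1) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("read_trace: ", path, " is not RIFF/WAVE")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("read_trace: ", path, " is not RIFF/WAVE")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("read_trace: ", path, " is missing its fmt or data chunk")
  if (fmt$channels != 1)
    stop("read_trace: only mono WAV is supported (got ", fmt$channels,
         " channels)")
  values <- if (fmt$audio_format == 3 && fmt$bits == 32) {
    readBin(data_raw, "double", length(data_raw) / 4, 4, endian = "little")
  } else if (fmt$audio_format == 1 && fmt$bits == 16) {
    readBin(data_raw, "integer", length(data_raw) / 2, 2, signed = TRUE,
            endian = "little") / 32767 * scale
  } else {
    stop("read_trace: unsupported WAV encoding (format ", fmt$audio_format,
         ", ", fmt$bits, " bits)")
  }
  digitized_trace(values, rate = fmt$sample_rate)
}

write_wav <- function(trace, path, encoding = c("float32", "pcm16"),
                      scale = 1) {
  encoding <- match.arg(encoding)
  rate <- as.integer(round(trace$rate))
  if (abs(rate - trace$rate) > 1e-6)
    stop("write_trace: WAV requires an integer sampling rate (got ",
         trace$rate, " Hz)")
  n <- length(trace$values)
  if (encoding == "float32") {
    audio_format <- 2L + 1L; bits <- 32L
    payload_size <- 4L * n
  } else {
    audio_format <- 1L; bits <- 16L
    payload_size <- 2L * n
  }
  block_align <- bits %/% 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + payload_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(as.integer(audio_format), con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                    # mono
  writeBin(rate, con, 4, endian = "little")
  writeBin(as.integer(rate * block_align), con, 4, endian = "little")
  writeBin(as.integer(block_align), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(payload_size), con, 4, endian = "little")
  if (encoding == "float32") {
    writeBin(trace$values, con, 4, endian = "little")
  } else {
    x <- as.integer(round(pmin(pmax(trace$values / scale, -1), 1) * 32767))
    writeBin(x, con, 2, endian = "little")
  }
  invisible(path)
}

#' Write an events table
#'
#' Tab-separated events file with the conventional `onset` / `duration` /
#' `trial_type` columns; times in seconds printed to 0.1 µs.
#'
#' @param x a schedule data frame (from [stimulus_train()] /
#'   [oddball_sequence()]) or a [pulse_train()].
#' @param path destination.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  if (inherits(x, "pulse_train")) x <- as.data.frame(x)
  stopifnot(is.data.frame(x),
            all(c("onset", "duration", "trial_type") %in% names(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("onset\tduration\ttrial_type", con)
  if (nrow(x))
    writeLines(sprintf("%.7f\t%.7f\t%s", x$onset, x$duration,
                       as.character(x$trial_type)), con)
  invisible(path)
}

#' Read an events table written by [write_events()]
#'
#' @param path file to read.
#' @return data frame with `onset`, `duration`, `trial_type`.
#' @export
read_events <- function(path) {
  utils::read.delim(path, colClasses = c("numeric", "numeric", "character"))
}

#' Read a run configuration file
#'
#' YAML with optional top-level keys `device` (see [config_to_device()]),
#' `bench` (parameter overrides for the characterization benches), `seed`,
#' and `out`.
#'
#' @param path YAML file.
#' @return the configuration as a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Build a device from a configuration list
#'
#' Expects `cfg$channels`: a list of channel entries, each with `kind`
#' (`"trigger"` or `"switch"`), optional `front_end` (`"half_wave"` /
#' `"dc_biased"`), and the corresponding [trigger_config()] /
#' [switch_config()] parameters.  Top-level `trigger_cost`, `switch_cost`,
#' and `loop_overhead` are honoured.
#'
#' @param cfg a list, typically the `device` element of [read_run_config()].
#' @param sampling_frequency default rate written into trigger channels.
#' @return a [device_config()].
#' @export
config_to_device <- function(cfg, sampling_frequency = 6250) {
  stopifnot(is.list(cfg), length(cfg$channels) >= 1)
  chans <- lapply(cfg$channels, function(ch) {
    fe <- channel_front_end(if (is.null(ch$front_end)) "half_wave" else ch$front_end)
    kind <- if (is.null(ch$kind)) "trigger" else ch$kind
    conf <- if (identical(kind, "switch")) {
      switch_config(
        debounce_time = ch$debounce_time %||% 20000,
        refractory_period = ch$refractory_period %||% 1e5,
        pulse_duration = ch$pulse_duration %||% 10000)
    } else {
      trigger_config(
        sampling_frequency = ch$sampling_frequency %||% sampling_frequency,
        threshold = ch$threshold %||% 50,
        min_pulse_duration = ch$min_pulse_duration %||% 10000,
        pulse_increment = ch$pulse_increment %||% 0,
        refractory_period = ch$refractory_period %||% 1e5)
    }
    device_channel(conf, fe, line_id = ch$line_id %||% NULL)
  })
  device_config(chans,
                trigger_cost = cfg$trigger_cost %||% 16.5,
                switch_cost = cfg$switch_cost %||% 0.5,
                loop_overhead = cfg$loop_overhead %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run manifest
#'
#' Records the package version, the command, every parameter and every seed
#' of a run as JSON, sufficient to rerun the command.  Identical
#' configuration and seed produce a byte-identical manifest.
#'
#' @param dir output directory (created if needed).
#' @param command the subcommand or function name.
#' @param params named list of parameters (seeds included).
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, params) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(package = "triggerbench",
         version = as.character(utils::packageVersion("triggerbench")),
         command = command, params = params),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
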