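#' Uniformly sampled voltage trace
#'
#' The universal signal carrier of the package: a uniformly sampled
#' single-channel voltage series in millivolts, with its sampling rate and
#' start time. All filters and detectors operate on `eag_trace` objects.
#'
#' @param samples Numeric vector of voltages (mV). Must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds of the first sample. Default 0.
#' @return An object of class `eag_trace`: a numeric vector with attributes
#'   `fs` and `t0`.
#' @examples
#' tr <- eag_trace(sin(2 * pi * 5 * seq(0, 1, by = 0.01)), fs = 100)
#' trace_duration(tr)
#' @export
eag_trace <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("trace must contain at least one sample", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("trace samples must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("`t0` must be a single finite number (s)", call. = FALSE)
  structure(samples, fs = as.numeric(fs), t0 = as.numeric(t0),
            class = "eag_trace")
}

#' @export
print.eag_trace <- function(x, ...) {
  cat(sprintf("<eag_trace> %d samples @ %g Hz, t0 = %g s, range [%.4g, %.4g] mV\n",
              length(x), trace_fs(x), trace_t0(x),
              min(x), max(x)))
  invisible(x)
}

#' Trace accessors
#'
#' @param trace An [eag_trace()] (or any object carrying `fs`/`t0`
#'   attributes, such as a counter trace).
#' @return `trace_fs`: sampling rate (Hz); `trace_t0`: start time (s);
#'   `trace_times`: vector of sample times (s); `trace_duration`: duration
#'   in seconds (n / fs).
#' @export
trace_fs <- function(trace) attr(trace, "fs")

#' @rdname trace_fs
#' @export
trace_t0 <- function(trace) {
  t0 <- attr(trace, "t0")
  if (is.null(t0)) 0 else t0
}

#' @rdname trace_fs
#' @export
trace_times <- function(trace) {
  trace_t0(trace) + (seq_along(unclass(trace)) - 1) / trace_fs(trace)
}

#' @rdname trace_fs
#' @export
trace_duration <- function(trace) length(trace) / trace_fs(trace)

#' @export
as.data.frame.eag_trace <- function(x, ...) {
  data.frame(time_s = trace_times(x), voltage_mv = as.numeric(x))
}

assert_trace <- function(trace, arg = "trace") {
  if (!inherits(trace, "eag_trace"))
    stop(sprintf("`%s` must be an eag_trace", arg), call. = FALSE)
  if (!all(is.finite(unclass(trace))))
    stop(sprintf("`%s` contains non-finite samples", arg), call. = FALSE)
  invisible(trace)
}

#' Read and write voltage traces as delimited text
#'
#' Traces are exchanged as CSV with columns `time_s,voltage_mv` (the
#' sampling rate is recovered from the time column) or a single
#' `voltage_mv` column with `fs` supplied by the caller. Writing uses 15
#' significant digits so a round trip is lossless to well below 1e-9 mV.
#'
#' @param trace An [eag_trace()].
#' @param path File path.
#' @param time_column Write the `time_s` column (default `TRUE`).
#' @param fs Sampling rate in Hz, required when the file has no `time_s`
#'   column.
#' @return `write_trace`: the path, invisibly. `read_trace`: an
#'   [eag_trace()].
#' @export
write_trace <- function(trace, path, time_column = TRUE) {
  assert_trace(trace)
  if (time_column) {
    df <- data.frame(time_s = sprintf("%.15g", trace_times(trace)),
                     voltage_mv = sprintf("%.15g", as.numeric(trace)))
  } else {
    df <- data.frame(voltage_mv = sprintf("%.15g", as.numeric(trace)))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, fs = NULL) {
  df <- utils::read.csv(path)
  if ("time_s" %in% names(df) && nrow(df) >= 2) {
    dt <- diff(df$time_s)
    fs_file <- 1 / stats::median(dt)
    if (max(abs(dt - 1 / fs_file)) > 0.01 / fs_file)
      stop("`time_s` column is not uniformly sampled", call. = FALSE)
    if (is.null(fs)) fs <- fs_file
    t0 <- df$time_s[1]
  } else {
    if (is.null(fs))
      stop("`fs` is required when the file has no time_s column",
           call. = FALSE)
    t0 <- 0
  }
  if (!"voltage_mv" %in% names(df))
    stop("expected a `voltage_mv` column", call. = FALSE)
  eag_trace(df$voltage_mv, fs = fs, t0 = t0)
}

#' Odour stimulus train
#'
#' The solenoid-valve trigger sequence: puff onset times plus a common puff
#' duration. Serves both as ground truth for evaluating detections and as
#' the driving input of the synthetic generator.
#'
#' @param onsets Strictly increasing vector of onset times (s).
#' @param duration Puff duration (s); must be shorter than every
#'   inter-onset interval.
#' @return An object of class `stimulus_train` with fields `onsets` and
#'   `duration`.
#' @seealso [make_stimulus_train()] for the regular-frequency constructor,
#'   [stim_to_trace()] to render as a binary waveform.
#' @export
stimulus_train <- function(onsets, duration) {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 1L || !all(is.finite(onsets)))
    stop("`onsets` must be a non-empty finite vector", call. = FALSE)
  if (is.unsorted(onsets, strictly = TRUE))
    stop("`onsets` must be strictly increasing", call. = FALSE)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stop("`duration` must be a single positive number (s)", call. = FALSE)
  if (length(onsets) > 1L && any(diff(onsets) <= duration))
    stop("inter-onset intervals must exceed the puff duration",
         call. = FALSE)
  structure(list(onsets = onsets, duration = as.numeric(duration)),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("<stimulus_train> %d puffs of %g s, onsets %g..%g s\n",
              length(x$onsets), x$duration, min(x$onsets), max(x$onsets)))
  invisible(x)
}

#' Render a stimulus train as a binary trace
#'
#' Produces the rectangular valve-trigger waveform: 1 while the valve is
#' open (from each onset for `duration` seconds), 0 otherwise, sampled at
#' `fs`.
#'
#' @param stim A [stimulus_train()].
#' @param fs Sampling rate (Hz).
#' @param duration_s Total length of the rendered trace (s). Defaults to
#'   the last offset plus one second.
#' @param t0 Start time (s).
#' @return An [eag_trace()] of 0/1 values.
#' @export
stim_to_trace <- function(stim, fs, duration_s = NULL, t0 = 0) {
  stopifnot(inherits(stim, "stimulus_train"))
  if (is.null(duration_s))
    duration_s <- max(stim$onsets) + stim$duration + 1
  n <- round(duration_s * fs)
  t <- t0 + (seq_len(n) - 1) / fs
  y <- numeric(n)
  for (on in stim$onsets) {
    y[t >= on & t < on + stim$duration] <- 1
  }
  eag_trace(y, fs = fs, t0 = t0)
}

#' Read and write stimulus trains as CSV
#'
#' Files have columns `onset_s,duration_s` (the duration is repeated on
#' every row for simplicity of the format).
#'
#' @param stim A [stimulus_train()].
#' @param path File path.
#' @return `write_stimulus`: the path, invisibly; `read_stimulus`: a
#'   [stimulus_train()].
#' @export
write_stimulus <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus_train"))
  df <- data.frame(onset_s = sprintf("%.15g", stim$onsets),
                   duration_s = sprintf("%.15g", stim$duration))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("onset_s", "duration_s") %in% names(df)))
    stop("expected columns onset_s,duration_s", call. = FALSE)
  stimulus_train(df$onset_s, df$duration_s[1])
}
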