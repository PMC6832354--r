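#' D-Counter parameters
#'
#' Parameter bundle for the dropping-counter detector. The window length
#' in samples is derived as `w = round(s_win * fs)` and must be at least
#' 2. The depth threshold `th` is *relative* to the window's first sample
#' and must be strictly negative: with `th >= 0` the reset branch would
#' fire on every window (the deepest drop is initialised at 0), making the
#' detector inert, so such values are rejected.
#'
#' @param s_win Window length in seconds (> 0). Detection latency equals
#'   `s_win`, since a window's count is available once its last sample has
#'   arrived.
#' @param th Relative depth threshold in mV (< 0). A window's count is
#'   zeroed unless some sample lies at least this far below the window's
#'   first sample.
#' @param fs Sampling rate (Hz) the parameters are bound to.
#' @return An object of class `dcounter_params`.
#' @export
dcounter_params <- function(s_win, th, fs) {
  if (!is.numeric(s_win) || length(s_win) != 1L || s_win <= 0)
    stop("`s_win` must be a single positive number (s)", call. = FALSE)
  if (!is.numeric(th) || length(th) != 1L || !is.finite(th) || th >= 0)
    stop("`th` must be strictly negative (relative depth, mV)",
         call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number (Hz)", call. = FALSE)
  w <- as.integer(round(s_win * fs))
  if (w < 2L)
    stop("window must span at least 2 samples (round(s_win * fs) >= 2)",
         call. = FALSE)
  structure(list(s_win = s_win, th = th, fs = fs, w = w),
            class = "dcounter_params")
}

#' @export
print.dcounter_params <- function(x, ...) {
  cat(sprintf("<dcounter_params> s_win = %g s (w = %d samples @ %g Hz), th = %g mV\n",
              x$s_win, x$w, x$fs, x$th))
  invisible(x)
}

#' Dropping counter over a single window
#'
#' The core of the D-Counter detector. The window's first sample is the
#' reference; every sample strictly below it increments the counter, and
#' the deepest drop (initialised at 0) is tracked. If the deepest drop
#' does not reach the threshold `th` the count is reset to 0, so shallow
#' jitter never produces a count. Because only differences within the
#' window enter, the count is invariant to any constant baseline offset --
#' this is what defeats slow drift.
#'
#' @param window Numeric vector of at least 2 voltage samples (mV).
#' @param th Relative depth threshold (mV, < 0).
#' @return Integer count in `[0, length(window) - 1]`.
#' @examples
#' d_counter_window(c(0, -0.2, -0.6), th = -0.5)  # 2
#' d_counter_window(c(0, -0.2, -0.6), th = -0.7)  # 0 (too shallow)
#' @export
d_counter_window <- function(window, th) {
  window <- as.numeric(window)
  if (length(window) < 2L)
    stop("window must contain at least 2 samples", call. = FALSE)
  if (!all(is.finite(window)))
    stop("window contains non-finite samples", call. = FALSE)
  if (!is.numeric(th) || length(th) != 1L || !is.finite(th) || th >= 0)
    stop("`th` must be strictly negative", call. = FALSE)
  as.integer(d_counter_cpp(window, length(window), th))
}

#' Sliding D-Counter over a trace
#'
#' Applies [d_counter_window()] to every window of `w = round(s_win * fs)`
#' samples at stride 1. The count of the window starting at sample `n` is
#' attributed to reference index `n`; in a causal system it becomes
#' available at sample `n + w - 1`, i.e. with latency `s_win`.
#'
#' @param trace An [eag_trace()] of length at least `w`.
#' @param params A [dcounter_params()] whose `fs` matches the trace.
#' @return A `counter_trace`: an integer vector of `length(trace) - w + 1`
#'   counts with attributes `fs`, `t0` (time of the first reference
#'   sample), `w` and `th`.
#' @export
d_counter_stream <- function(trace, params) {
  assert_trace(trace)
  stopifnot(inherits(params, "dcounter_params"))
  if (abs(params$fs - trace_fs(trace)) > 1e-9)
    stop("`params$fs` does not match the trace sampling rate", call. = FALSE)
  w <- params$w
  if (length(trace) < w)
    stop("trace is shorter than one window", call. = FALSE)
  counts <- d_counter_cpp(as.numeric(trace), w, params$th)
  structure(as.integer(counts),
            fs = trace_fs(trace), t0 = trace_t0(trace),
            w = w, th = params$th, s_win = params$s_win,
            class = "counter_trace")
}

#' @export
print.counter_trace <- function(x, ...) {
  cat(sprintf("<counter_trace> %d counts @ %g Hz (w = %d, th = %g mV), max count %d\n",
              length(x), attr(x, "fs"), attr(x, "w"), attr(x, "th"),
              max(as.integer(x))))
  invisible(x)
}

#' @export
as.data.frame.counter_trace <- function(x, ...) {
  data.frame(t_s = trace_times(x), count = as.integer(x))
}

#' Write a counter trace as CSV (`t_s,count`)
#'
#' @param counter A `counter_trace` from [d_counter_stream()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_counter <- function(counter, path) {
  stopifnot(inherits(counter, "counter_trace"))
  df <- data.frame(t_s = sprintf("%.15g", trace_times(counter)),
                   count = as.integer(counter))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fixed-threshold baseline detector
#'
#' The conventional comparator the D-Counter is measured against: emits 1
#' wherever the voltage lies strictly below an absolute (not relative)
#' negative threshold, 0 elsewhere. Sensitive to baseline drift by
#' construction, since the comparison is against an absolute level.
#'
#' @param trace An [eag_trace()].
#' @param th_abs Absolute voltage threshold (mV, < 0).
#' @return An [eag_trace()] of 0/1 values, same length and rate.
#' @examples
#' fixed_threshold(eag_trace(c(-0.6, 0, -0.4), fs = 100), th_abs = -0.5)
#' @export
fixed_threshold <- function(trace, th_abs) {
  assert_trace(trace)
  if (!is.numeric(th_abs) || length(th_abs) != 1L || !is.finite(th_abs) ||
      th_abs >= 0)
    stop("`th_abs` must be strictly negative (mV)", call. = FALSE)
  eag_trace(as.numeric(as.numeric(trace) < th_abs),
            fs = trace_fs(trace), t0 = trace_t0(trace))
}

#' Extract discrete detection events from a detector output
#'
#' Turns a counter trace (or a binary fixed-threshold trace) into discrete
#' response intervals: maximal runs of samples at or above `c_min` become
#' events, and events separated by less than `merge_gap_s` are merged into
#' one (a refractory rule that keeps the ringing of a single response from
#' being counted twice). Event onset is the time of the first reference
#' sample of the run.
#'
#' The defaults operationalise "the counter indicates a response": at
#' least half the window dropping below the reference (`c_min =
#' ceiling(w/2)`), and a merge gap of 0.3 s, shorter than the minimum 1 s
#' inter-stimulus interval of the puff protocols.
#'
#' @param x A `counter_trace` from [d_counter_stream()], or a binary
#'   [eag_trace()] from [fixed_threshold()].
#' @param c_min Minimum count for a sample to belong to an event. For a
#'   counter trace must lie in `[1, w - 1]`; for a binary trace it is
#'   fixed at 1.
#' @param merge_gap_s Events closer than this gap (s) are merged
#'   (`>= 0`).
#' @return An object of class `detection_events`: a list with a
#'   data.frame `events` (`onset_s`, `offset_s`) plus the parameters used.
#' @export
extract_events <- function(x, c_min = NULL, merge_gap_s = 0.3) {
  if (!is.numeric(merge_gap_s) || length(merge_gap_s) != 1L ||
      merge_gap_s < 0)
    stop("`merge_gap_s` must be >= 0", call. = FALSE)
  if (inherits(x, "counter_trace")) {
    w <- attr(x, "w")
    if (is.null(c_min)) c_min <- ceiling(w / 2)
    if (!is.numeric(c_min) || length(c_min) != 1L || c_min < 1 ||
        c_min > w - 1)
      stop("`c_min` must lie in [1, w - 1]", call. = FALSE)
    vals <- as.integer(x)
  } else if (inherits(x, "eag_trace")) {
    vals <- as.numeric(x)
    if (!all(vals %in% c(0, 1)))
      stop("expected a binary trace (output of fixed_threshold())",
           call. = FALSE)
    if (is.null(c_min)) c_min <- 1
  } else {
    stop("`x` must be a counter_trace or a binary eag_trace", call. = FALSE)
  }
  fs <- attr(x, "fs")
  times <- trace_times(x)

  active <- vals >= c_min
  events <- run_intervals(active, times, fs)
  events <- merge_close_events(events, merge_gap_s)
  structure(list(events = events, c_min = c_min,
                 merge_gap_s = merge_gap_s, fs = fs),
            class = "detection_events")
}

run_intervals <- function(active, times, fs) {
  if (!any(active))
    return(data.frame(onset_s = numeric(0), offset_s = numeric(0)))
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(onset_s = times[starts[keep]],
             offset_s = times[ends[keep]] + 1 / fs)
}

merge_close_events <- function(events, gap) {
  n <- nrow(events)
  if (n <= 1L) return(events)
  keep_onset <- events$onset_s[1]
  out <- list()
  cur_on <- events$onset_s[1]; cur_off <- events$offset_s[1]
  for (i in 2:n) {
    if (events$onset_s[i] - cur_off < gap) {
      cur_off <- events$offset_s[i]
    } else {
      out[[length(out) + 1L]] <- c(cur_on, cur_off)
      cur_on <- events$onset_s[i]; cur_off <- events$offset_s[i]
    }
  }
  out[[length(out) + 1L]] <- c(cur_on, cur_off)
  m <- do.call(rbind, out)
  data.frame(onset_s = m[, 1], offset_s = m[, 2])
}

#' @export
print.detection_events <- function(x, ...) {
  cat(sprintf("<detection_events> %d events (c_min = %g, merge_gap = %g s)\n",
              nrow(x$events), x$c_min, x$merge_gap_s))
  if (nrow(x$events) > 0) print(utils::head(x$events, 10))
  invisible(x)
}

#' Write detection events as CSV (`onset_s,offset_s`)
#'
#' @param events A `detection_events` object.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "detection_events"))
  df <- events$events
  df$onset_s <- sprintf("%.15g", df$onset_s)
  df$offset_s <- sprintf("%.15g", df$offset_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Score detection events against the stimulus train
#'
#' Greedy one-to-one matching: walking through the stimuli in time order,
#' each stimulus claims the earliest unclaimed event whose interval
#' `[onset_s, offset_s]` overlaps the acceptance window
#' `[onset, onset + tol_s]`. Matching on interval overlap rather than on
#' the event onset alone keeps the score robust to the refractory merge:
#' a brief noise blip merging into the front of a true detection shifts
#' the event onset earlier but leaves the interval covering the response.
#' Stimuli left unclaimed are misses; events left unclaimed are false
#' alarms.
#'
#' @param events A `detection_events` object.
#' @param stim A [stimulus_train()] (ground truth).
#' @param tol_s Matching tolerance after each stimulus onset (s, > 0).
#'   The default 0.5 s allows for response latency plus the detector's
#'   window latency.
#' @return A list with `hits`, `misses`, `false_alarms` and a `pairs`
#'   data.frame of matched (stimulus, event) onsets.
#' @export
match_events <- function(events, stim, tol_s = 0.5) {
  stopifnot(inherits(events, "detection_events"),
            inherits(stim, "stimulus_train"))
  if (!is.numeric(tol_s) || length(tol_s) != 1L || tol_s <= 0)
    stop("`tol_s` must be > 0", call. = FALSE)
  ev_on <- events$events$onset_s
  ev_off <- events$events$offset_s
  claimed <- rep(FALSE, length(ev_on))
  pairs <- list()
  for (s_on in stim$onsets) {
    cand <- which(!claimed & ev_off >= s_on & ev_on <= s_on + tol_s)
    if (length(cand) > 0) {
      j <- cand[which.min(ev_on[cand])]
      claimed[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(s_on, ev_on[j])
    }
  }
  hits <- length(pairs)
  pairs_df <- if (hits > 0) {
    m <- do.call(rbind, pairs)
    data.frame(stim_onset_s = m[, 1], event_onset_s = m[, 2])
  } else {
    data.frame(stim_onset_s = numeric(0), event_onset_s = numeric(0))
  }
  list(hits = hits,
       misses = length(stim$onsets) - hits,
       false_alarms = sum(!claimed),
       pairs = pairs_df)
}
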