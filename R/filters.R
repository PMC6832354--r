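#' Conditional exponential moving average filter
#'
#' Direction-dependent first-order recursive smoother designed to enhance
#' the negative transients of odour-evoked EAG responses. When the raw
#' signal falls between consecutive samples the new sample is weighted by
#' the smoothing factor `alpha`; when it rises (or stays equal) the weight
#' is `1 - alpha`. With `alpha > 0.5` the filter therefore tracks downward
#' deflections quickly while heavily smoothing rises, so baseline recovery
#' and upward noise excursions are attenuated relative to the negative
#' response peaks:
#'
#' \deqn{y[n] = \begin{cases}
#'   \alpha x[n] + (1-\alpha) y[n-1] & x[n] - x[n-1] < 0 \\
#'   (1-\alpha) x[n] + \alpha y[n-1] & \text{otherwise}
#' \end{cases}}
#'
#' with `y[0] = x[0]`. The tie case (zero difference) takes the rising
#' branch because the falling branch is entered only on a strictly
#' negative difference. The branch depends on the *input* difference, not
#' the filter state.
#'
#' @param trace An [eag_trace()].
#' @param alpha Smoothing factor, strictly between 0 and 1. Values of 0.7
#'   or 0.9 are typical for 100 Hz EAG traces.
#' @return An [eag_trace()] of the same length, sampling rate and start
#'   time, with attribute `ema_alpha` recording the factor used.
#' @examples
#' tr <- eag_trace(c(0, -1, -1, 0, 0), fs = 100)
#' conditional_ema(tr, alpha = 0.7)
#' @export
conditional_ema <- function(trace, alpha) {
  assert_trace(trace)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("`alpha` must satisfy 0 < alpha < 1", call. = FALSE)
  y <- cond_ema_cpp(as.numeric(trace), alpha)
  out <- eag_trace(y, fs = trace_fs(trace), t0 = trace_t0(trace))
  attr(out, "ema_alpha") <- alpha
  out
}

# Split a decimation factor into stages of at most `max_stage` so that the
# anti-aliasing FIR stays short. Non-divisible factors fall back to a
# single stage.
decimation_stages <- function(q, max_stage = 10L) {
  stages <- integer(0)
  while (q > max_stage) {
    d <- max_stage
    while (d > 1L && q %% d != 0L) d <- d - 1L
    if (d == 1L) break  # prime factor larger than max_stage: single stage
    stages <- c(stages, d)
    q <- q %/% d
  }
  c(stages, q)
}

#' Decimate a trace to a lower sampling rate
#'
#' Reduces the sampling rate by an integer factor. By default an
#' anti-aliasing FIR low-pass (Hamming-windowed, cut-off at 0.8 times the
#' target Nyquist frequency, applied forward and backward for zero phase)
#' precedes sample selection, so components above the new Nyquist rate --
#' notably 50--70 Hz power-line hum when decimating to 100 Hz -- cannot
#' alias into the sub-10 Hz response band. Large factors are decimated in
#' stages of at most 10. `method = "subsample"` skips the filter and
#' selects every q-th raw sample, provided for fidelity experiments with
#' acquisition systems that resample naively.
#'
#' @param trace An [eag_trace()].
#' @param target_fs Target sampling rate (Hz); `fs / target_fs` must be a
#'   positive integer (upsampling is refused).
#' @param method `"fir"` (anti-aliased, default) or `"subsample"` (naive
#'   picking).
#' @return An [eag_trace()] at `target_fs` covering the same time span to
#'   within one output sample.
#' @export
decimate_trace <- function(trace, target_fs, method = c("fir", "subsample")) {
  assert_trace(trace)
  method <- match.arg(method)
  fs <- trace_fs(trace)
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0)
    stop("`target_fs` must be a single positive number (Hz)", call. = FALSE)
  if (target_fs > fs)
    stop("`target_fs` exceeds the trace sampling rate (no upsampling)",
         call. = FALSE)
  q <- fs / target_fs
  if (abs(q - round(q)) > 1e-8)
    stop("fs / target_fs must be an integer decimation factor", call. = FALSE)
  q <- as.integer(round(q))
  if (q == 1L) return(trace)

  x <- as.numeric(trace)
  if (method == "subsample") {
    y <- x[seq(1L, length(x), by = q)]
    return(eag_trace(y, fs = target_fs, t0 = trace_t0(trace)))
  }
  for (d in decimation_stages(q)) {
    if (d == 1L) next
    # 0.8 * target Nyquist, normalised to the current Nyquist
    ntaps <- 10L * d  # transition band comfortably inside 0.8..1 x Nyquist/d
    b <- signal::fir1(ntaps, 0.8 / d, type = "low")
    x <- signal::filtfilt(signal::Ma(b), x)
    x <- x[seq(1L, length(x), by = d)]
  }
  eag_trace(x, fs = target_fs, t0 = trace_t0(trace))
}

#' Causal high-pass reference filter
#'
#' A second-order Butterworth high-pass applied forward only (causal, as a
#' real-time system would run it). Provided as the conventional remedy for
#' baseline drift, and to demonstrate its failure mode on EAG data: the
#' odour response itself lives below 10 Hz, so a high-pass deep enough to
#' remove drift also attenuates the response peaks (see the methods
#' vignette).
#'
#' @param trace An [eag_trace()].
#' @param cutoff Cut-off frequency (Hz), strictly between 0 and the
#'   Nyquist frequency.
#' @return An [eag_trace()] of the same length and rate with the DC
#'   component removed.
#' @export
highpass_reference <- function(trace, cutoff) {
  assert_trace(trace)
  fs <- trace_fs(trace)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 ||
      cutoff >= fs / 2)
    stop("`cutoff` must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "high")
  y <- as.numeric(signal::filter(bf, as.numeric(trace)))
  eag_trace(y, fs = fs, t0 = trace_t0(trace))
}
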