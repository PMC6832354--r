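#' Regular odour stimulus train
#'
#' Builds the puff protocol used throughout: `n` puffs of `duration`
#' seconds delivered at a constant frequency, onsets at `k / freq` for
#' `k = 0 .. n-1`. Typical protocols use 10 puffs of 0.2 s at 0.25, 0.5
#' or 1 Hz.
#'
#' @param freq Puff frequency (Hz, > 0).
#' @param n Number of puffs (>= 1).
#' @param duration Puff duration (s), strictly less than the period
#'   `1/freq`.
#' @return A [stimulus_train()].
#' @examples
#' make_stimulus_train(0.25, n = 10)  # onsets 0, 4, ..., 36 s
#' @export
make_stimulus_train <- function(freq, n, duration = 0.2) {
  if (!is.numeric(freq) || length(freq) != 1L || freq <= 0)
    stop("`freq` must be a single positive number (Hz)", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be >= 1", call. = FALSE)
  if (duration >= 1 / freq)
    stop("puff duration must be shorter than the period 1/freq",
         call. = FALSE)
  stimulus_train(onsets = (seq_len(n) - 1) / freq, duration = duration)
}

#' Biexponential odour-response kernel
#'
#' Template waveform of a single odour-evoked EAG deflection: zero before
#' the stimulus, then a negative transient
#' `A * (exp(-t/tau_decay) - exp(-t/tau_rise))` scaled so its minimum
#' equals `amplitude`. The default time constants (rise 0.05 s, decay
#' 0.3 s) place essentially all of the kernel's spectral power below
#' 10 Hz, matching the band occupied by real odour responses.
#'
#' @param t Time points (s); values `< 0` return 0.
#' @param amplitude Peak (most negative) value in mV (< 0).
#' @param tau_rise Rise time constant (s), `0 < tau_rise < tau_decay`.
#' @param tau_decay Decay time constant (s).
#' @return Numeric vector of kernel values (mV) at `t`.
#' @export
response_kernel <- function(t, amplitude = -1, tau_rise = 0.05,
                            tau_decay = 0.3) {
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude >= 0)
    stop("`amplitude` must be negative (mV)", call. = FALSE)
  if (!is.numeric(tau_rise) || !is.numeric(tau_decay) ||
      tau_rise <= 0 || tau_decay <= tau_rise)
    stop("time constants must satisfy 0 < tau_rise < tau_decay",
         call. = FALSE)
  # unscaled shape peaks at t* = log(tau_decay/tau_rise) / (1/tau_rise - 1/tau_decay)
  tstar <- log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)
  peak <- exp(-tstar / tau_decay) - exp(-tstar / tau_rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (amplitude / peak) *
    (exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise))
  out
}

#' Synthetic EAG configuration
#'
#' Full parameterisation of the synthetic EAG generator. The generator
#' emulates the four recording conditions observed on an antenna-bearing
#' drone: the cross of motor/propeller noise off/on with odour
#' absent/present. Baseline drift and residual power-line hum are present
#' in every condition (both arise from the electrode and mains, not the
#' motors); broadband noise is added only when motor noise is on; the
#' response train is added only when odour is on.
#'
#' Component defaults (see the methods vignette for the calibration
#' rationale):
#' * response: per-puff amplitude drawn uniformly from
#'   `[-1.5, -0.7]` mV (within the observed single-response range of
#'   about -1.8 to 0.5 mV, with pulse-to-pulse variability), biexponential
#'   kernel with rise 0.05 s / decay 0.3 s.
#' * drift: Gaussian random walk with step 0.2 mV per sqrt(second),
#'   softly reflected at +/- 0.5 mV, plus an optional slow sinusoid
#'   (disabled by default).
#' * hum: 0.1 mV sinusoid at 60 Hz with random phase. Requires
#'   `fs > 2 * hum_freq` whenever its amplitude is nonzero, so hum is
#'   generated at its true frequency; aliasing, if wanted, must come from
#'   explicit naive subsampling.
#' * broadband: white Gaussian noise, SD 0.25 mV (motor-noise conditions
#'   only). Calibrated jointly with the drift bound so that, with odour
#'   off, well under 1% of samples fall below -1.0 mV: background noise
#'   alone stays clear of the response amplitude range.
#' * vibration: band-limited (below 25 Hz) Gaussian noise, SD 0.15 mV
#'   (motor-noise conditions only). Propeller and frame vibration
#'   transmitted to the antenna mount is concentrated at low frequencies,
#'   so unlike the white component it survives anti-aliased decimation
#'   and contaminates the response band -- this is what makes the
#'   unfiltered D-Counter noisy on motor-on recordings.
#'
#' Each component draws from its own random substream derived from the
#' master seed, so disabling one component does not change the others.
#'
#' @param condition One of `"noise_off"`, `"noise_off_odour"`,
#'   `"noise_on"`, `"noise_on_odour"`.
#' @param fs Sampling rate (Hz) of the generated trace. Default 1000 Hz,
#'   standing in for a high-rate acquisition front end; decimate to
#'   100 Hz with [decimate_trace()] for the detection pipeline.
#' @param duration_s Trace duration (s). `NULL` (default) extends 3 s past
#'   the last puff offset.
#' @param stim_freq,stim_n,stim_duration Puff protocol passed to
#'   [make_stimulus_train()].
#' @param amp_range Per-puff amplitude range (mV, both negative).
#' @param tau_rise,tau_decay Kernel time constants (s).
#' @param latency_s Delay from valve onset to response onset (s).
#' @param drift_step Random-walk step (mV per sqrt(s)); 0 disables.
#' @param drift_bound Soft reflecting bound on the walk (mV).
#' @param drift_sine_amp,drift_sine_freq Optional slow sinusoidal drift
#'   (mV, Hz); amplitude 0 disables.
#' @param hum_amp,hum_freq Power-line hum amplitude (mV) and frequency
#'   (Hz, conventionally in 50--70 Hz).
#' @param broadband_sd White-noise SD (mV) used in the motor-noise
#'   conditions.
#' @param vibration_sd SD (mV) of the band-limited motor-vibration noise;
#'   0 disables.
#' @param vibration_cutoff Upper edge (Hz) of the vibration band.
#' @param seed Master integer seed; fully determines the output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(condition = c("noise_on_odour", "noise_off",
                                     "noise_off_odour", "noise_on"),
                       fs = 1000, duration_s = NULL,
                       stim_freq = 0.5, stim_n = 10, stim_duration = 0.2,
                       amp_range = c(-1.5, -0.7),
                       tau_rise = 0.05, tau_decay = 0.3, latency_s = 0.25,
                       drift_step = 0.2, drift_bound = 0.5,
                       drift_sine_amp = 0, drift_sine_freq = 0.1,
                       hum_amp = 0.1, hum_freq = 60,
                       broadband_sd = 0.25,
                       vibration_sd = 0.15, vibration_cutoff = 25,
                       seed = 1L) {
  condition <- match.arg(condition)
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be > 0", call. = FALSE)
  if (hum_amp > 0 && fs <= 2 * hum_freq)
    stop("`fs` must exceed twice the hum frequency when hum is enabled",
         call. = FALSE)
  if (length(amp_range) != 2L || any(amp_range >= 0))
    stop("`amp_range` must be two negative values (mV)", call. = FALSE)
  amp_range <- sort(amp_range)
  vals <- c(stim_freq, stim_n, stim_duration, tau_rise, tau_decay,
            latency_s, drift_step, drift_bound, drift_sine_amp,
            drift_sine_freq, hum_amp, hum_freq, broadband_sd,
            vibration_sd, vibration_cutoff)
  if (!all(is.finite(vals)))
    stop("all configuration values must be finite", call. = FALSE)
  if (any(c(drift_step, drift_sine_amp, hum_amp, broadband_sd,
            vibration_sd) < 0))
    stop("component amplitudes must be >= 0", call. = FALSE)
  if (vibration_sd > 0 && vibration_cutoff >= fs / 2)
    stop("`vibration_cutoff` must lie below the Nyquist frequency",
         call. = FALSE)
  seed <- as.integer(seed)
  structure(list(condition = condition, fs = fs, duration_s = duration_s,
                 stim_freq = stim_freq, stim_n = stim_n,
                 stim_duration = stim_duration,
                 amp_range = amp_range, tau_rise = tau_rise,
                 tau_decay = tau_decay, latency_s = latency_s,
                 drift_step = drift_step, drift_bound = drift_bound,
                 drift_sine_amp = drift_sine_amp,
                 drift_sine_freq = drift_sine_freq,
                 hum_amp = hum_amp, hum_freq = hum_freq,
                 broadband_sd = broadband_sd,
                 vibration_sd = vibration_sd,
                 vibration_cutoff = vibration_cutoff, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s, fs = %g Hz, %d puffs @ %g Hz, seed = %d\n",
              x$condition, x$fs, x$stim_n, x$stim_freq, x$seed))
  invisible(x)
}

# Reflect a vector into [-b, b] (mirror folding, handles large excursions).
reflect_into <- function(x, b) {
  if (b <= 0) return(x * 0)
  y <- (x + b) %% (4 * b)
  ifelse(y > 2 * b, 4 * b - y, y) - b
}

# Per-component substream seeds, drawn from the master seed in a fixed
# order so that disabling a component never reshuffles the others.
substream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  s <- sample.int(2147483646L, 5L)
  names(s) <- c("response", "drift", "hum", "broadband", "vibration")
  s
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  expr
}

#' Generate a synthetic EAG trace
#'
#' Superposes the enabled components of a [sim_config()] -- odour-response
#' train, baseline drift, power-line hum, broadband and band-limited
#' motor noise -- into a single voltage trace, and returns it together
#' with the ground-truth stimulus train. The same seed always yields the
#' identical trace; components use independent substreams, so the trace
#' of a full configuration equals the sample-wise sum of the components
#' generated in isolation under the same seed.
#'
#' @param config A [sim_config()].
#' @param components Optional character subset of
#'   `c("response", "drift", "hum", "broadband", "vibration")` to render
#'   in isolation (still gated by the condition). Default: all.
#' @return A list with `trace` (an [eag_trace()]) and `stim` (a
#'   [stimulus_train()]).
#' @export
generate_eag <- function(config,
                         components = c("response", "drift", "hum",
                                        "broadband", "vibration")) {
  stopifnot(inherits(config, "sim_config"))
  components <- match.arg(components, several.ok = TRUE)
  odour_on <- config$condition %in% c("noise_off_odour", "noise_on_odour")
  motors_on <- config$condition %in% c("noise_on", "noise_on_odour")

  stim <- make_stimulus_train(config$stim_freq, config$stim_n,
                              config$stim_duration)
  dur <- config$duration_s
  if (is.null(dur)) dur <- max(stim$onsets) + stim$duration + 3
  fs <- config$fs
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  seeds <- substream_seeds(config$seed)
  x <- numeric(n)

  if (odour_on && "response" %in% components) {
    amps <- with_seed(seeds[["response"]],
                      stats::runif(length(stim$onsets),
                                   config$amp_range[1],
                                   config$amp_range[2]))
    # kernel support: 6 decay constants captures > 99.99% of the transient
    kt <- seq(0, 6 * config$tau_decay, by = 1 / fs)
    kern <- response_kernel(kt, amplitude = -1,
                            tau_rise = config$tau_rise,
                            tau_decay = config$tau_decay)
    for (j in seq_along(stim$onsets)) {
      i0 <- round((stim$onsets[j] + config$latency_s) * fs) + 1L
      idx <- i0:min(n, i0 + length(kern) - 1L)
      if (idx[1] > n) next
      x[idx] <- x[idx] + abs(amps[j]) * kern[seq_along(idx)]
    }
  }

  if ("drift" %in% components &&
      (config$drift_step > 0 || config$drift_sine_amp > 0)) {
    d <- numeric(n)
    if (config$drift_step > 0) {
      steps <- with_seed(seeds[["drift"]],
                         stats::rnorm(n, 0, config$drift_step / sqrt(fs)))
      d <- reflect_into(cumsum(steps), config$drift_bound)
    }
    if (config$drift_sine_amp > 0) {
      phase <- with_seed(seeds[["drift"]] + 1L, stats::runif(1, 0, 2 * pi))
      d <- d + config$drift_sine_amp *
        sin(2 * pi * config$drift_sine_freq * t + phase)
    }
    x <- x + d
  }

  if ("hum" %in% components && config$hum_amp > 0) {
    phase <- with_seed(seeds[["hum"]], stats::runif(1, 0, 2 * pi))
    x <- x + config$hum_amp * sin(2 * pi * config$hum_freq * t + phase)
  }

  if (motors_on && "broadband" %in% components &&
      config$broadband_sd > 0) {
    x <- x + with_seed(seeds[["broadband"]],
                       stats::rnorm(n, 0, config$broadband_sd))
  }

  if (motors_on && "vibration" %in% components &&
      config$vibration_sd > 0) {
    white <- with_seed(seeds[["vibration"]], stats::rnorm(n))
    bf <- signal::butter(2, config$vibration_cutoff / (fs / 2),
                         type = "low")
    v <- as.numeric(signal::filtfilt(bf, white))
    x <- x + v * (config$vibration_sd / stats::sd(v))
  }

  list(trace = eag_trace(x, fs = fs), stim = stim)
}

#' Drifting-baseline scenario
#'
#' A preset configuration emulating the classic failure case of absolute
#' thresholds: a clean (motors-off) recording whose baseline wanders by
#' about +/- 0.5 mV on a timescale of tens of seconds while response
#' amplitudes vary from puff to puff. When a weak puff lands on a positive
#' drift excursion its absolute level stays above -0.5 mV and a fixed
#' threshold at that level misses it, while the drop relative to the local
#' baseline is still deep enough for the D-Counter.
#'
#' @param seed Master seed.
#' @param stim_freq Puff frequency (Hz).
#' @return A [sim_config()].
#' @export
sim_config_drifting <- function(seed = 1L, stim_freq = 0.25) {
  sim_config(condition = "noise_off_odour", seed = seed,
             stim_freq = stim_freq,
             amp_range = c(-1.4, -0.65),
             drift_step = 0.05, drift_bound = 0.3,
             drift_sine_amp = 0.5, drift_sine_freq = 0.05)
}

#' Write a simulation configuration as YAML
#'
#' Everything needed to reproduce a generated trace exactly, including the
#' seed.
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  lst <- unclass(config)
  lst$duration_s <- if (is.null(lst$duration_s)) "auto" else lst$duration_s
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (identical(lst$duration_s, "auto")) lst$duration_s <- NULL
  do.call(sim_config, lst)
}
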