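test_that("stimulus protocol arithmetic matches the puff schedule", {
  st <- make_stimulus_train(0.25, n = 10, duration = 0.2)
  expect_equal(st$onsets, seq(0, 36, by = 4))
  expect_equal(st$duration, 0.2)

  st1 <- make_stimulus_train(1, n = 10)
  expect_equal(max(st1$onsets) - min(st1$onsets), 9)

  expect_equal(make_stimulus_train(0.5, n = 1)$onsets, 0)
  expect_error(make_stimulus_train(0.5, n = 10, duration = 2.5),
               "shorter than the period")
  expect_error(make_stimulus_train(0, n = 10), "positive")
})

test_that("response kernel starts at zero and attains the requested depth", {
  t <- seq(-0.1, 3, by = 1e-4)
  k <- response_kernel(t, amplitude = -1.2)
  expect_equal(k[t < 0], rep(0, sum(t < 0)))
  expect_equal(response_kernel(0, amplitude = -1.2), 0)
  # evaluate at the analytic argmin of the biexponential
  tau_r <- 0.05; tau_d <- 0.3
  tstar <- log(tau_d / tau_r) / (1 / tau_r - 1 / tau_d)
  expect_equal(response_kernel(tstar, amplitude = -1.2), -1.2,
               tolerance = 1e-9)
  expect_gte(min(k), -1.2 - 1e-9)
  expect_error(response_kernel(t, amplitude = 0.5), "negative")
  expect_error(response_kernel(t, amplitude = -1, tau_rise = 0.5,
                               tau_decay = 0.3), "tau")
})

test_that("a kernel train concentrates its power below 10 Hz", {
  fs <- 1000
  st <- make_stimulus_train(0.5, n = 10)
  cfg <- sim_config(condition = "noise_off_odour", fs = fs, seed = 5,
                    drift_step = 0, hum_amp = 0)
  g <- generate_eag(cfg, components = "response")
  spec <- psd_welch(g$trace, segment_s = 1)
  df <- diff(spec$freq_hz[1:2])
  frac <- sum(spec$psd[spec$freq_hz < 10]) / sum(spec$psd)
  expect_gt(frac, 0.9)
})

test_that("generation is seed-deterministic", {
  cfg <- sim_config(seed = 9)
  a <- generate_eag(cfg)
  b <- generate_eag(cfg)
  expect_identical(as.numeric(a$trace), as.numeric(b$trace))
  expect_identical(a$stim$onsets, b$stim$onsets)

  c2 <- generate_eag(sim_config(seed = 10))
  expect_false(identical(as.numeric(a$trace), as.numeric(c2$trace)))
})

test_that("the full trace is the superposition of its isolated components", {
  cfg <- sim_config(condition = "noise_on_odour", seed = 6)
  full <- generate_eag(cfg)$trace
  parts <- lapply(c("response", "drift", "hum", "broadband", "vibration"),
                  function(cmp) as.numeric(generate_eag(cfg, cmp)$trace))
  expect_equal(as.numeric(full), Reduce(`+`, parts), tolerance = 1e-12)
})

test_that("with all noise sources silenced the trace is the pure kernel train", {
  cfg <- sim_config(condition = "noise_off_odour", seed = 7,
                    drift_step = 0, drift_sine_amp = 0, hum_amp = 0)
  g <- generate_eag(cfg)
  resp <- generate_eag(cfg, components = "response")
  expect_identical(as.numeric(g$trace), as.numeric(resp$trace))
  expect_gte(min(as.numeric(g$trace)), -1.8)
  expect_lte(max(as.numeric(g$trace)), 0.5)
})

test_that("hum peaks in the 50-70 Hz mains band and drift stays below 1 Hz", {
  cfg <- sim_config(condition = "noise_on", seed = 8, duration_s = 30)
  hum <- generate_eag(cfg, components = "hum")$trace
  spec <- psd_welch(hum, segment_s = 1)
  f_peak <- spec$freq_hz[which.max(spec$psd)]
  expect_gte(f_peak, 50)
  expect_lte(f_peak, 70)

  # long segments so the sub-hertz band is resolved (0.1 Hz bins)
  drift <- generate_eag(cfg, components = "drift")$trace
  sd_ <- psd_welch(drift, segment_s = 10)
  frac_low <- sum(sd_$psd[sd_$freq_hz < 1]) / sum(sd_$psd)
  expect_gt(frac_low, 0.5)
})

test_that("motor noise alone rarely reaches response-like amplitudes", {
  # pooled across 20 seeds: fraction of samples below -1.0 mV under 1%
  fr <- vapply(1:20, function(s) {
    g <- generate_eag(sim_config(condition = "noise_on", seed = s,
                                 duration_s = 20))
    mean(as.numeric(g$trace) < -1.0)
  }, numeric(1))
  expect_lt(mean(fr), 0.01)
})

test_that("a clean odour trace yields exactly one matched event per puff", {
  for (s in 1:5) {
    g <- generate_eag(sim_config(condition = "noise_off_odour", seed = s))
    tr <- decimate_trace(g$trace, 100)
    pl <- detect_pipeline(tr, ema = TRUE, alpha = 0.7, s_win = 0.1,
                          th = -0.5)
    m <- match_events(pl$events, g$stim)
    expect_equal(m$hits, length(g$stim$onsets))
    expect_equal(nrow(pl$events$events), length(g$stim$onsets))
  }
})

test_that("simulation configs survive a YAML round trip", {
  cfg <- sim_config(condition = "noise_on_odour", stim_freq = 0.25,
                    seed = 42)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back[names(back) != "seed"], cfg[names(cfg) != "seed"])
  expect_identical(generate_eag(back)$trace, generate_eag(cfg)$trace)
})

test_that("configuration validation rejects unrepresentable hum and bad ranges", {
  expect_error(sim_config(fs = 100, hum_freq = 60, hum_amp = 0.1),
               "twice the hum frequency")
  expect_silent(sim_config(fs = 100, hum_amp = 0))
  expect_error(sim_config(amp_range = c(-1, 0.5)), "negative")
  expect_error(sim_config(broadband_sd = -1), ">= 0")
})
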