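test_that("single-window dropping counter follows the published pseudocode", {
  expect_equal(d_counter_window(c(0, 0, 0), th = -0.5), 0L)
  # two drops, deepest -0.6 reaches th = -0.5: count kept
  expect_equal(d_counter_window(c(0, -0.2, -0.6), th = -0.5), 2L)
  # deepest drop -0.6 shallower than th = -0.7: reset branch fires
  expect_equal(d_counter_window(c(0, -0.2, -0.6), th = -0.7), 0L)
  # strictly decreasing window deeper than th counts every non-reference sample
  win <- seq(0, -1, length.out = 8)
  expect_equal(d_counter_window(win, th = -0.5), 7L)

  expect_error(d_counter_window(c(0), th = -0.5), "at least 2")
  expect_error(d_counter_window(c(0, -1), th = 0), "negative")
  expect_error(d_counter_window(c(0, -1), th = 0.5), "negative")
})

test_that("sliding D-Counter matches hand-executed windows", {
  # constant trace: every window counts zero
  ct <- d_counter_stream(eag_trace(rep(1, 100), fs = 100),
                         dcounter_params(s_win = 0.1, th = -0.5, fs = 100))
  expect_length(ct, 91)
  expect_true(all(as.integer(ct) == 0L))

  # two hand-executed windows of w = 3: [0, -0.2, -0.6] has two drops and
  # a deepest drop of -0.6 <= th, so the count survives; [-0.2, -0.6, -0.6]
  # also has two drops but its deepest drop relative to the new reference
  # is only -0.4 > th, so the reset zeroes it
  tr <- eag_trace(c(0, -0.2, -0.6, -0.6), fs = 10)
  p <- dcounter_params(s_win = 0.3, th = -0.5, fs = 10)
  expect_equal(p$w, 3L)
  expect_equal(as.integer(d_counter_stream(tr, p)), c(2L, 0L))
  expect_identical(as.integer(d_counter_stream(tr, p)),
                   dcount_stream_oracle(c(0, -0.2, -0.6, -0.6), 3L, -0.5))

  expect_error(d_counter_stream(eag_trace(c(0, 1), fs = 10), p),
               "shorter than one window")
})

test_that("sliding D-Counter equals the literal window-by-window oracle", {
  set.seed(11)
  for (w in c(3L, 10L, 20L)) {
    for (rep in 1:10) {
      x <- rnorm(200, sd = 0.5)
      th <- -runif(1, 0.1, 1)
      got <- as.integer(d_counter_stream(
        eag_trace(x, fs = 100),
        dcounter_params(s_win = w / 100, th = th, fs = 100)))
      expect_identical(got, dcount_stream_oracle(x, w, th))
    }
  }
})

test_that("counts are bounded by the window and w-1 needs an all-dropping window", {
  set.seed(12)
  w <- 10L
  p <- dcounter_params(s_win = 0.1, th = -0.3, fs = 100)
  for (rep in 1:20) {
    x <- rnorm(150, sd = 0.4)
    ct <- as.integer(d_counter_stream(eag_trace(x, fs = 100), p))
    expect_true(all(ct >= 0L & ct <= w - 1L))
    # count w-1 iff every non-reference sample is below the reference and
    # the deepest drop reaches th
    full <- which(ct == w - 1L)
    for (i in full) {
      win <- x[i:(i + w - 1L)]
      expect_true(all(win[-1] < win[1]))
      expect_lte(min(win - win[1]), -0.3)
    }
  }
})

test_that("the D-Counter is translation invariant but not scale invariant", {
  set.seed(13)
  x <- rnorm(200, sd = 0.4)
  p <- dcounter_params(s_win = 0.1, th = -0.5, fs = 100)
  a <- as.integer(d_counter_stream(eag_trace(x, fs = 100), p))
  b <- as.integer(d_counter_stream(eag_trace(x + 3.7, fs = 100), p))
  expect_identical(a, b)

  # scaling changes counts when a drop straddles th: one clean window
  win <- c(rep(0, 5), rep(-0.6, 5))  # drop depth 0.6
  tr1 <- eag_trace(c(win, rep(0, 10)), fs = 100)
  tr2 <- eag_trace(0.5 * c(win, rep(0, 10)), fs = 100)  # depth 0.3 < |th|
  c1 <- as.integer(d_counter_stream(tr1, p))
  c2 <- as.integer(d_counter_stream(tr2, p))
  expect_gt(max(c1), 0L)
  expect_equal(max(c2), 0L)
})

test_that("deepening the relative threshold never increases a count", {
  set.seed(14)
  for (rep in 1:10) {
    x <- rnorm(150, sd = 0.4)
    tr <- eag_trace(x, fs = 100)
    ths <- c(-0.2, -0.4, -0.6, -0.9)
    counts <- sapply(ths, function(th) {
      as.integer(d_counter_stream(tr, dcounter_params(0.1, th, 100)))
    })
    # columns ordered from shallow to deep threshold
    for (j in 2:length(ths)) {
      expect_true(all(counts[, j] <= counts[, j - 1]))
    }
  }
})

test_that("fixed threshold is a strict elementwise comparator", {
  tr <- eag_trace(c(-0.6, 0, -0.4), fs = 100)
  expect_equal(as.numeric(fixed_threshold(tr, -0.5)), c(1, 0, 0))
  expect_equal(as.numeric(fixed_threshold(eag_trace(rep(0, 5), 100), -0.5)),
               rep(0, 5))
  # samples exactly at the threshold do not trigger (strict <)
  expect_equal(as.numeric(fixed_threshold(eag_trace(rep(-0.5, 4), 100), -0.5)),
               rep(0, 4))
  expect_error(fixed_threshold(tr, 0.5), "negative")
})

test_that("fixed threshold commutes with time reversal; the D-Counter does not", {
  set.seed(15)
  x <- rnorm(200, sd = 0.4)
  fwd <- as.numeric(fixed_threshold(eag_trace(x, 100), -0.3))
  rev_ <- as.numeric(fixed_threshold(eag_trace(rev(x), 100), -0.3))
  expect_equal(rev(rev_), fwd)

  p <- dcounter_params(0.1, -0.5, 100)
  cf <- as.integer(d_counter_stream(eag_trace(x, 100), p))
  cr <- as.integer(d_counter_stream(eag_trace(rev(x), 100), p))
  # the counter looks for drops, a time-asymmetric feature
  expect_false(identical(rev(cr), cf))
})

test_that("event extraction finds runs, honours c_min and merges close events", {
  counts <- structure(c(0L, 5L, 6L, 0L, 0L, 0L, 7L, 0L),
                      fs = 100, t0 = 0, w = 10L, th = -0.5,
                      class = "counter_trace")
  ev0 <- extract_events(counts, c_min = 5, merge_gap_s = 0)
  expect_equal(nrow(ev0$events), 2)
  ev1 <- extract_events(counts, c_min = 5, merge_gap_s = 0.1)
  expect_equal(nrow(ev1$events), 1)

  none <- structure(rep(0L, 20), fs = 100, t0 = 0, w = 10L, th = -0.5,
                    class = "counter_trace")
  expect_equal(nrow(extract_events(none)$events), 0)

  expect_error(extract_events(counts, c_min = 0), "c_min")
  expect_error(extract_events(counts, c_min = 10), "c_min")
  expect_error(extract_events(counts, c_min = 5, merge_gap_s = -1),
               "merge_gap_s")
})

test_that("events are sorted, non-overlapping and onset precedes offset", {
  set.seed(16)
  for (rep in 1:10) {
    cfg <- sim_config(condition = "noise_on_odour", seed = rep)
    g <- generate_eag(cfg)
    tr <- decimate_trace(g$trace, 100)
    pl <- detect_pipeline(tr, s_win = 0.1)
    ev <- pl$events$events
    if (nrow(ev) > 0) {
      expect_true(all(ev$onset_s < ev$offset_s))
      if (nrow(ev) > 1) {
        expect_true(all(diff(ev$onset_s) > 0))
        expect_true(all(ev$onset_s[-1] >= ev$offset_s[-nrow(ev)]))
      }
    }
  }
})

test_that("event-to-stimulus matching is greedy, one-to-one and tolerant", {
  stim <- stimulus_train(c(0, 2, 4), 0.2)
  mk <- function(onsets, offsets) {
    structure(list(events = data.frame(onset_s = onsets,
                                       offset_s = offsets),
                   c_min = 5, merge_gap_s = 0.3, fs = 100),
              class = "detection_events")
  }
  # events exactly at the stimulus onsets
  m <- match_events(mk(c(0, 2, 4), c(0.3, 2.3, 4.3)), stim)
  expect_equal(m$hits, 3)
  expect_equal(m$misses, 0)
  expect_equal(m$false_alarms, 0)

  # no events at all
  m2 <- match_events(mk(numeric(0), numeric(0)), stim)
  expect_equal(m2$misses, 3)
  expect_equal(m2$hits, 0)

  # one spurious event far from any stimulus
  m3 <- match_events(mk(c(0, 1.2, 2, 4), c(0.3, 1.25, 2.3, 4.3)), stim)
  expect_equal(m3$hits, 3)
  expect_equal(m3$false_alarms, 1)

  # an event can serve at most one stimulus
  m4 <- match_events(mk(0.1, 0.4), stimulus_train(c(0, 0.3), 0.2),
                     tol_s = 0.5)
  expect_equal(m4$hits, 1)
  expect_equal(m4$misses, 1)
})
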