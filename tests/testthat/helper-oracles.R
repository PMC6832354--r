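# Shared cache so expensive benchmark tables are computed once per run.
.bench_cache <- new.env(parent = emptyenv())

# Literal, loop-by-loop transcriptions of the published pseudocode.
# Deliberately independent of the package implementation (no shared code
# paths): these serve as oracles for exact-equivalence tests.

# Plain exponential moving average: y[0] = x[0];
# y[n] = a*x[n] + (1-a)*y[n-1].
ema_oracle <- function(x, a) {
  y <- numeric(length(x))
  y[1] <- x[1]
  if (length(x) > 1) {
    for (n in 2:length(x)) y[n] <- a * x[n] + (1 - a) * y[n - 1]
  }
  y
}

# Conditional EMA: falling samples use factor a, others 1 - a.
cond_ema_oracle <- function(x, a) {
  y <- numeric(length(x))
  y[1] <- x[1]
  if (length(x) > 1) {
    for (n in 2:length(x)) {
      if (x[n] - x[n - 1] < 0) {
        y[n] <- a * x[n] + (1 - a) * y[n - 1]
      } else {
        y[n] <- (1 - a) * x[n] + a * y[n - 1]
      }
    }
  }
  y
}

# Dropping counter for one window, transcribed statement by statement:
# reference = first sample, count drops below it, track the deepest
# drop starting from 0, reset the count unless the deepest drop reaches
# th.
dcount_window_oracle <- function(win, th) {
  counter <- 0L
  dmax <- 0
  for (i in seq_along(win)) {
    delta <- win[i] - win[1]
    if (delta < 0) {
      counter <- counter + 1L
      if (delta < dmax) dmax <- delta
    }
  }
  if (dmax > th) counter <- 0L
  counter
}

# Sliding application of the window oracle at stride 1.
dcount_stream_oracle <- function(x, w, th) {
  vapply(seq_len(length(x) - w + 1L), function(i) {
    dcount_window_oracle(x[i:(i + w - 1L)], th)
  }, integer(1))
}
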