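test_that("band-pass passes the pulse band and rejects out-of-band tones", {
  t <- seq(0, 60 - 0.01, by = 0.01)
  gain_at <- function(f0) {
    y <- bandpass(ppg_record(sin(2 * pi * f0 * t), 100))$signal
    max(Mod(stats::fft(y)) / length(y) * 2)  # FFT amplitude oracle
  }
  expect_true(gain_at(1.2) >= 0.9 && gain_at(1.2) <= 1.1)
  expect_lte(gain_at(0.1), 0.1)   # >= 20 dB down
  expect_lte(gain_at(8), 0.1)
})

test_that("band-pass preserves length, rate and zeros, and is linear", {
  rec <- ppg_record(rep(0, 1000), 100)
  out <- bandpass(rec)
  expect_identical(out$signal, rep(0, 1000))
  expect_equal(out$fs, 100)
  x <- sin(2 * pi * 1.3 * seq(0, 9.99, 0.01)) + rnorm(1000, 0, 0.1)
  a <- 3.7
  y1 <- bandpass(ppg_record(a * x, 100))$signal
  y2 <- a * bandpass(ppg_record(x, 100))$signal
  expect_equal(y1, y2, tolerance = 1e-8)
})

test_that("sampling rate too low for the band is a configuration error", {
  expect_error(bandpass(ppg_record(rnorm(100), 25),
                        filter_params(high_cut = 13)), "too low")
})

test_that("window enumeration follows the half-open counting contract", {
  expect_equal(nrow(window_iter(180, window_params(30, 10))), 16)
  expect_equal(nrow(window_iter(180, window_params(120, 10))), 7)
  expect_equal(nrow(window_iter(20, window_params(30, 10))), 0)
  w <- window_iter(100, window_params(30, 10))
  expect_equal(w$start, (seq_len(nrow(w)) - 1) * 10)
  expect_true(all(w$end <= 100))
  # property: counts match floor arithmetic across random durations
  set.seed(5)
  for (i in 1:25) {
    T <- runif(1, 1, 500); ws <- runif(1, 1, 150)
    ss <- runif(1, 0.5, ws)
    n_expected <- if (T >= ws) floor((T - ws) / ss) + 1 else 0
    expect_equal(nrow(window_iter(T, window_params(ws, ss))), n_expected)
  }
})

test_that("resampling preserves duration, identity and amplitude", {
  rec <- ppg_record(sin(2 * pi * 1.0 * seq(0, 8 - 0.01, 0.01)), 100)
  expect_identical(resample_record(rec, 100), rec)
  out <- resample_record(rec, 64)
  expect_length(out$signal, 512)
  amp <- diff(range(out$signal[33:480])) / 2  # interior, away from edges
  expect_lt(abs(amp - 1), 0.02)
  expect_error(resample_record(rec, 10), "target_fs")
})
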