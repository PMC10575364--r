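test_that("pSQI behaves correctly for pure tones and constants", {
  t <- seq(0, 30 - 0.01, by = 0.01)
  expect_gte(psqi(sin(2 * pi * 1.2 * t), 100), 95)
  expect_lte(psqi(sin(2 * pi * 8 * t), 100), 5)
  expect_warning(v <- psqi(rep(3, 3000), 100), "constant")
  expect_equal(v, 0)
  expect_warning(psqi(sin(2 * pi * 1.2 * t[1:500]), 100), "shorter")
})

test_that("pSQI equals a direct FFT band-power ratio", {
  set.seed(3)
  t <- seq(0, 30 - 0.01, by = 0.01)
  x <- sin(2 * pi * 1.2 * t) + rnorm(length(t), 0, sqrt(0.5))  # ~0 dB SNR
  got <- psqi(x, 100)
  # independent oracle: direct periodogram summation
  xc <- x - mean(x)
  pw <- Mod(stats::fft(xc))^2
  freq <- (seq_along(xc) - 1) * 100 / length(xc)
  keep <- freq <= 50
  pw <- pw[keep]; freq <- freq[keep]
  want <- 100 * sum(pw[freq >= 0.7 & freq <= 4]) /
    sum(pw[freq > 0 & freq <= 10])
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("pSQI decreases monotonically with added broadband noise", {
  t <- seq(0, 30 - 0.01, by = 0.01)
  clean <- sin(2 * pi * 1.1 * t)
  levels <- c(0, 0.3, 0.8, 2)
  means <- vapply(levels, function(a) {
    mean(vapply(1:8, function(s) {
      set.seed(s)
      psqi(clean + a * rnorm(length(t)), 100)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("quality gating drops low-pSQI windows from both series", {
  wm <- function(v) windowed_metrics(seq(0, by = 10, length.out = length(v)),
                                     v, 30, 10)
  test <- wm(c(70, 71, 72)); ref <- wm(c(70.5, 71.5, 72.5))
  qs <- wm(c(50, 30, 60)); attr(qs, "metric") <- "psqi_pct"
  g <- quality_gate(test, ref, qs)
  expect_equal(g$mask, c(TRUE, FALSE, TRUE))
  expect_equal(g$test$value, c(70, 72))
  expect_equal(g$ref$value, c(70.5, 72.5))
  # paired-discard invariant: never drops one side only
  expect_identical(g$test$start, g$ref$start)
  # mismatched grids are an alignment error
  bad <- windowed_metrics(c(0, 10, 20), c(1, 2, 3), 60, 10)
  expect_error(quality_gate(test, bad, qs), "grid")
})

test_that("gating a simulated session matches a brute-force recount", {
  st <- simulate_study(study_protocol(n_subjects = 1,
                                      condition_duration = 120, seed = 23))
  sess <- st$sessions[[4]]  # movement condition
  wp <- window_params(30, 10)
  ibi_dev <- estimate_ibi(sess$device)
  ibi_ref <- estimate_ibi(sess$reference)
  g <- quality_gate(hr_windowed(ibi_dev, wp), hr_windowed(ibi_ref, wp),
                    sess$device)  # gate on the artifact-laden channel
  qs <- psqi_windowed(sess$device, wp)
  expect_equal(sum(g$mask), sum(qs$value >= 40, na.rm = TRUE))
})

test_that("best-channel selection is a per-window argmax with stable ties", {
  cr <- clean_recording(duration = 60, seed = 51)
  wp <- window_params(30, 10)
  w <- window_iter(cr$record, wp)
  mk_q <- function(scores_per_window) {
    # constant quality inside each window via a fine quality vector
    quality_vector(rep(scores_per_window[1], 120), res = 0.5)
  }
  ear_scores <- c(0.9, 0.2, 0.9, 0.2)
  fin_scores <- c(0.4, 0.7, 0.4, 0.7)
  ear_q <- windowed_metrics(w$start, ear_scores, 30, 10, "psqi_pct")
  fin_q <- windowed_metrics(w$start, fin_scores, 30, 10, "psqi_pct")
  chans <- list(ear = list(record = cr$record, quality = ear_q),
                finger = list(record = cr$record, quality = fin_q))
  pick <- select_best_channel(chans, wp)
  expect_equal(pick$channel,
               ifelse(ear_scores >= fin_scores, "ear", "finger"))
  # single channel is always chosen; exact tie goes to the first
  expect_true(all(select_best_channel(chans["ear"], wp)$channel == "ear"))
  tie <- list(a = list(record = cr$record, quality = ear_q),
              b = list(record = cr$record, quality = ear_q))
  expect_true(all(select_best_channel(tie, wp)$channel == "a"))
})
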