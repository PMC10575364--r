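test_that("flat or empty signals yield no beats", {
  expect_length(detect_beats(ppg_record(rep(0, 1000), 100)), 0)
  expect_length(detect_beats(ppg_record(rep(2.5, 1000), 100)), 0)
})

test_that("beat detection recovers simulated beats and their times", {
  cr <- clean_recording(mean_hr = 72, jitter_sd = 25, duration = 170,
                        seed = 41)
  b <- detect_beats(bandpass(cr$record))
  expect_length(b, length(cr$ibi))
  err_ms <- abs(attr(b, "times") - attr(cr$record, "peak_times")) * 1000
  expect_lt(mean(err_ms), 20)
})

test_that("equal-height maxima in one refractory span keep the earliest", {
  x <- rep(0, 400)
  x[100] <- 1; x[110] <- 1      # 100 ms apart at fs=100, same height
  b <- detect_beats(ppg_record(x, 100),
                    beat_detector_params(min_ibi_ms = 330))
  expect_identical(as.integer(b), 100L)
})

test_that("interval conversion applies the healthy-range screen", {
  b <- c(1L, 81L, 161L)
  ibi <- ibi_from_beats(b, 100)
  expect_equal(ibi$intervals, c(800, 800))
  # a 3000 ms gap (missed beats) is discarded and counted
  b2 <- structure(c(1L, 81L, 381L), times = c(0, 0.8, 3.8))
  ibi2 <- ibi_from_beats(b2, 100)
  expect_equal(ibi2$intervals, 800)
  expect_equal(attr(ibi2, "n_discarded"), 1L)
  expect_length(ibi_from_beats(c(5L), 100), 0)
})

test_that("ground-truth beat times round-trip through ibi_from_beats", {
  cr <- clean_recording(duration = 60, seed = 13)
  beat_times <- c(0, cr$ibi$times)
  b <- structure(round(beat_times * 100) + 1L, times = beat_times)
  est <- ibi_from_beats(b, 100)
  expect_equal(est$intervals, cr$ibi$intervals, tolerance = 1e-12)
})

test_that("windowed HR follows its estimator contract", {
  ibi <- ibi_series(rep(800, 225), cumsum(rep(0.8, 225)), duration = 180)
  hw <- hr_windowed(ibi)
  expect_equal(nrow(hw), 16)
  expect_true(all(abs(hw$value - 75) < 1e-9))
  # windows with < 2 intervals are NA
  sparse <- ibi_series(c(800, 810), c(0.8, 1.61), duration = 40)
  expect_true(all(is.na(hr_windowed(sparse)$value[2:nrow(hr_windowed(sparse))])))
})

test_that("pNN50 matches hand enumeration and is shift-invariant", {
  expect_equal(pnn50(c(800, 800, 800, 800)), 0)
  expect_equal(pnn50(c(800, 860, 800, 830)), 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(pnn50(800 + 60 * rep(c(1, -1), 10)), 100)
  expect_true(is.na(pnn50(c(800, 850))))
  # invariants on random series
  set.seed(8)
  for (i in 1:20) {
    iv <- runif(sample(3:50, 1), 400, 1500)
    v <- pnn50(iv)
    expect_gte(v, 0); expect_lte(v, 100)
    expect_equal(pnn50(iv + 123.4), v)
    # brute-force enumeration oracle
    expect_equal(v, 100 * mean(abs(diff(iv)) > 50))
  }
})

test_that("windowed pNN50 equals brute force over in-window intervals", {
  cr <- clean_recording(mean_hr = 70, jitter_sd = 40, duration = 180,
                        seed = 17)
  pw <- prv_windowed(cr$ibi)
  expect_equal(nrow(pw), 7)
  iv <- cr$ibi$intervals
  tt <- cr$ibi$times
  d <- diff(iv)
  dt <- tt[-1]
  for (k in seq_len(nrow(pw))) {
    sel <- dt >= pw$start[k] & dt < pw$start[k] + 120
    expect_equal(pw$value[k], 100 * mean(abs(d[sel]) > 50))
  }
  # zero-jitter series: all windows 0
  flat <- ibi_series(rep(800, 230), cumsum(rep(0.8, 230)), duration = 180)
  expect_true(all(prv_windowed(flat)$value == 0))
})

test_that("end-to-end pipeline recovers HR within 1 bpm across the range", {
  for (hr in c(50, 90, 150)) {
    sp <- simulation_spec(mean_hr = hr, jitter_sd = 0, duration = 120,
                          seed = hr + 1)
    rec <- render_ppg(generate_ibi_series(sp), sp$fs, sp$template)
    hw <- hr_windowed(estimate_ibi(rec))
    expect_true(all(abs(hw$value - hr) < 1), label = paste("hr", hr))
  }
})
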