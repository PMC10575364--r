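wm30 <- function(start, value) windowed_metrics(start, value, 30, 10)

test_that("pair alignment is time-keyed and drops incomplete windows", {
  a <- wm30(c(0, 10, 20), c(1, 2, 3))
  b <- wm30(c(0, 10, 20), c(1.1, 2.1, 3.1))
  p <- align_pairs(a, b)
  expect_equal(nrow(p), 3)
  a_na <- wm30(c(0, 10, 20), c(1, NA, 3))
  expect_equal(nrow(align_pairs(a_na, b)), 2)
  # order invariance
  a_sh <- wm30(c(20, 0, 10), c(3, 1, 2))
  expect_equal(align_pairs(a_sh, b), align_pairs(a, b),
               ignore_attr = TRUE)
  # different window parameters are an alignment error
  expect_error(align_pairs(a, windowed_metrics(c(0, 10), c(1, 2), 60, 10)),
               "different window")
})

test_that("agreement statistics match hand and brute-force oracles", {
  p0 <- data.frame(test = c(1, 2, 3), ref = c(1, 2, 3))
  s0 <- agreement_stats(p0)
  expect_equal(c(s0$rmse, s0$mae, s0$sd_error), c(0, 0, 0))
  expect_equal(s0$pearson_r, 1)
  s1 <- agreement_stats(data.frame(test = c(1, 2, 4), ref = c(1, 2, 3)))
  expect_equal(s1$rmse, sqrt(1 / 3), tolerance = 1e-9)    # 0.5774
  expect_equal(s1$mae, 1 / 3, tolerance = 1e-9)           # 0.3333
  expect_equal(s1$sd_error, sqrt(1 / 3), tolerance = 1e-9)
  expect_equal(s1$pearson_r, 0.9820, tolerance = 1e-3)
  # 1000 random pairs vs naive formula recomputation at 1e-9
  set.seed(14)
  pr <- data.frame(test = rnorm(1000, 70, 8), ref = rnorm(1000, 70, 8))
  st <- agreement_stats(pr)
  e <- pr$test - pr$ref
  expect_equal(st$rmse, sqrt(mean(e^2)), tolerance = 1e-9)
  expect_equal(st$mae, mean(abs(e)), tolerance = 1e-9)
  expect_equal(st$sd_error, stats::sd(e), tolerance = 1e-9)
  expect_equal(st$pearson_r, stats::cor(pr$test, pr$ref), tolerance = 1e-9)
  # constant reference: r undefined and flagged
  sc <- agreement_stats(data.frame(test = c(1, 2, 3), ref = c(5, 5, 5)))
  expect_true(is.na(sc$pearson_r))
  expect_false(attr(sc, "r_defined"))
})

test_that("Bland-Altman bias and limits match their definitions", {
  p <- data.frame(test = c(1, 2, 3), ref = c(1, 2, 3))
  ba <- bland_altman(p)
  expect_equal(c(ba$bias, ba$loa_low, ba$loa_high), c(0, 0, 0))
  p2 <- data.frame(test = c(6, 7, 8), ref = c(1, 2, 3))
  ba2 <- bland_altman(p2)
  expect_equal(ba2$bias, 5)
  expect_equal(ba2$loa_high - ba2$loa_low, 0)
  set.seed(9)
  p3 <- data.frame(test = rnorm(200), ref = rnorm(200))
  ba3 <- bland_altman(p3)
  d <- p3$test - p3$ref
  expect_equal(ba3$bias, mean(d), tolerance = 1e-12)
  expect_equal(ba3$loa_low, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba3$loa_high, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
  expect_equal(ba3$table$mean, (p3$test + p3$ref) / 2)
})

test_that("exact Wilcoxon p-values match full sign enumeration", {
  # n=5, all positive, one-sided
  w <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), alternative = "greater")
  expect_equal(w$p_value, 1 / 32)
  # symmetric +/- pairs: two-sided p = 1 at the midpoint statistic
  expect_warning(
    ws <- wilcoxon_signed_rank(c(1, -1, 2, -2)), "fewer than 5")
  expect_equal(ws$p_value, 1)
  expect_equal(ws$statistic, 4 * 5 / 4)
  # brute-force oracle: enumerate all 2^n sign assignments independently
  brute_p <- function(d, alternative) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% r
    p_ge <- mean(Ws >= W - 1e-9)
    p_le <- mean(Ws <= W + 1e-9)
    switch(alternative, greater = p_ge, less = p_le,
           two.sided = min(1, 2 * min(p_ge, p_le)))
  }
  set.seed(4)
  for (i in 1:6) {
    n <- sample(6:12, 1)
    d <- round(rnorm(n, 0.3, 1), 2)
    for (alt in c("two.sided", "greater", "less")) {
      got <- wilcoxon_signed_rank(d, alternative = alt)
      expect_equal(got$p_value, brute_p(d, alt), tolerance = 1e-12,
                   label = paste("n", n, alt))
    }
  }
  # cross-check against the reference implementation (no ties, exact)
  d2 <- c(1.3, -0.4, 2.2, 0.8, -1.9, 3.1, 0.6, -2.4, 1.1, 0.2)
  got <- wilcoxon_signed_rank(d2)
  want <- stats::wilcox.test(d2)$p.value
  expect_equal(got$p_value, want, tolerance = 1e-12)
  # degenerate input
  dg <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_true(dg$degenerate)
})

test_that("a zero-artifact study self-agrees in every condition", {
  proto <- study_protocol(n_subjects = 2, seed = 12)
  proto$conditions <- lapply(proto$conditions, function(sp) {
    sp$artifacts <- list(); sp
  })
  rep <- condition_report(simulate_study(proto))
  hr_rows <- rep$table[rep$table$metric == "hr_bpm", ]
  expect_true(all(hr_rows$rmse < 0.5))
  expect_true(all(hr_rows$pearson_r > 0.99, na.rm = TRUE))
})

test_that("artifact severity does not improve pooled pNN50 agreement", {
  pooled_r <- function(duty, seed) {
    proto <- study_protocol(
      conditions = list(only = simulation_spec(
        mean_hr = 70, jitter_sd = 35, jump_prob = 0.08, jump_magnitude = 60,
        artifacts = if (duty > 0) list(artifact_spec("motion_burst", duty,
                                                     3, 3)) else list())),
      n_subjects = 4, seed = seed)
    rep <- condition_report(simulate_study(proto))
    rep$table$pearson_r[rep$table$metric == "pnn50_pct" &
                          rep$table$condition == "combined"]
  }
  rs <- vapply(1:10, function(s) c(pooled_r(0.02, s), pooled_r(0.3, s)),
               numeric(2))
  expect_gte(mean(rs[1, ]), mean(rs[2, ]))
})

test_that("batch analysis equals looped single-file analysis and is stable", {
  td <- withr::local_tempdir()
  st <- simulate_study(study_protocol(n_subjects = 2,
                                      condition_duration = 60, seed = 33))
  write_study(st, td)
  out1 <- analyze_batch(td, list(metrics = c("hr", "psqi")))
  # 2 participants x 4 conditions x 2 metrics
  expect_equal(nrow(out1$summary), 16)
  expect_length(out1$errors, 0)
  # determinism: byte-identical summary on re-run
  h1 <- readBin(file.path(td, "summary.csv"), "raw",
                file.size(file.path(td, "summary.csv")))
  out2 <- analyze_batch(td, list(metrics = c("hr", "psqi")))
  h2 <- readBin(file.path(td, "summary.csv"), "raw",
                file.size(file.path(td, "summary.csv")))
  expect_identical(h1, h2)
  # equivalence with a direct single-file computation
  entry <- jsonlite::read_json(file.path(td, "manifest.json"),
                               simplifyVector = TRUE)[1, ]
  sess <- read_session(file.path(td, entry$device))
  rec <- ppg_record(sess$channels[[1]], sess$meta$fs)
  hw <- hr_windowed(estimate_ibi(rec), window_params(30, 10))
  row <- out1$summary[out1$summary$participant == "sub01" &
                        out1$summary$metric == "hr", ][1, ]
  expect_equal(row$mean, mean(hw$value, na.rm = TRUE), tolerance = 1e-9)
  # a corrupt file is logged, the batch continues
  writeLines("broken", file.path(td, entry$device))
  out3 <- analyze_batch(td, list(metrics = "hr"))
  expect_length(out3$errors, 1)
  expect_gt(nrow(out3$summary), 0)
})
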