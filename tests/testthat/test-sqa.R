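test_that("the model satisfies its shape and determinism contracts", {
  m1 <- build_sqa(seed = 3)
  m2 <- build_sqa(seed = 3)
  expect_identical(lapply(m1$layers, `[[`, "W"),
                   lapply(m2$layers, `[[`, "W"))
  expect_gt(m1$n_params, 0)
  q <- sqa_infer(m1, rep(0, 512))
  expect_length(q, 16)
  expect_true(all(is.finite(q$scores) & q$scores > 0 & q$scores < 1))
  expect_error(sqa_infer(m1, rep(0, 100)), "512")
  expect_error(sqa_config(input_s = 8.3), "multiple")
  expect_error(sqa_config(input_fs = 100), "stride-2")
})

test_that("training reduces the loss and enforces the subject-wise split", {
  fx <- sqa_fixture()
  h <- fx$model$history
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_true(all(fx$model$val_subjects %in% fx$corpus$subject))
  # no held-out subject contributed training segments by construction:
  # the split is on unique subject ids
  expect_gt(length(setdiff(unique(fx$corpus$subject),
                           fx$model$val_subjects)), 0)
  single <- list(x = fx$corpus$x[1:4, ], y = fx$corpus$y[1:4, ],
                 subject = rep(1L, 4))
  expect_error(train_sqa(build_sqa(seed = 1), single), "two subjects")
})

test_that("the trained model classifies clean and corrupted segments", {
  fx <- sqa_fixture()
  clean <- sqa_corpus(n_subjects = 2, duration = 60, seed = 88,
                      kinds = character(0))
  q <- sqa_infer(fx$model, clean$x[3, ])
  expect_gte(sum(quality_binary(q)), 14)
  q_flat <- sqa_infer(fx$model, rep(0.5, 512))
  expect_gte(sum(!quality_binary(q_flat)), 14)
})

test_that("label shuffling destroys held-out skill (negative control)", {
  corpus <- sqa_corpus(n_subjects = 6, duration = 120, seed = 55)
  shuffled <- corpus
  set.seed(2)
  shuffled$y <- corpus$y[sample(nrow(corpus$y)), ]
  m <- train_sqa(build_sqa(seed = 5), shuffled,
                 train_config(epochs = 6, seed = 5))
  acc <- m$history$val_acc[nrow(m$history)]
  is_val <- corpus$subject %in% m$val_subjects
  majority <- max(mean(shuffled$y[is_val, ] >= 0.5),
                  1 - mean(shuffled$y[is_val, ] >= 0.5))
  expect_lt(acc, majority + 0.05)
})

test_that("whole-recording annotation tiles per-segment inference", {
  fx <- sqa_fixture()
  cr <- clean_recording(duration = 80, fs = 64, seed = 61)
  ann <- annotate_recording(fx$model, cr$record)
  expect_length(ann, 160)
  # first two tiles equal direct per-segment inference
  for (k in 1:2) {
    seg <- cr$record$signal[((k - 1) * 512 + 1):(k * 512)]
    expect_equal(ann$scores[((k - 1) * 16 + 1):(k * 16)],
                 sqa_infer(fx$model, seg)$scores, tolerance = 1e-12)
  }
  # a 12 s record: 24 labels, the zero-padded tail beyond the signal is NA
  short <- ppg_record(cr$record$signal[1:768], 64)
  ann2 <- annotate_recording(fx$model, short)
  expect_length(ann2, 24)
  expect_true(all(!is.na(ann2$scores[1:24])))
})

test_that("quality annotations survive a session CSV round trip", {
  fx <- sqa_fixture()
  cr <- clean_recording(duration = 16, fs = 64, seed = 71)
  ann <- annotate_recording(fx$model, cr$record)
  td <- withr::local_tempdir()
  path <- file.path(td, "sess.csv")
  write_session(list(ppg = adc_quantize(cr$record$signal)), path, fs = 64,
                quality = list(ppg = ann))
  back <- read_session(path)$quality$ppg
  expect_equal(back$scores, ann$scores, tolerance = 1e-12)
})

test_that("checkpoints round-trip the model exactly", {
  fx <- sqa_fixture()
  td <- withr::local_tempdir()
  p <- file.path(td, "model.rds")
  save_sqa(fx$model, p)
  m2 <- load_sqa(p)
  x <- sqa_corpus(n_subjects = 2, duration = 30, seed = 3)$x[1, ]
  expect_identical(sqa_infer(m2, x)$scores, sqa_infer(fx$model, x)$scores)
})
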