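#' Configuration of the dense signal-quality model
#'
#' The model maps an 8 s PPG segment, resampled to a fixed internal rate,
#' to one quality score per 0.5 s sub-segment: a 1-D convolutional encoder
#' (strided downsampling) followed by a convolutional decoder stage that
#' reduces to `input_s / label_res` outputs squashed through a sigmoid.
#'
#' @param input_s segment length in seconds (default 8).
#' @param label_res label resolution in seconds (default 0.5).
#' @param input_fs internal sampling rate (default 64 Hz, so 512-sample
#'   inputs).
#' @param encoder_widths channel widths of the stride-2 encoder blocks.
#' @param decoder_width channel width of the stride-2 decoder stage.
#' @param kernel kernel size of all strided convolutions.
#' @return object of class `sqa_config`.
#' @export
sqa_config <- function(input_s = 8, label_res = 0.5, input_fs = 64,
                       encoder_widths = c(16, 32, 64, 64),
                       decoder_width = 32, kernel = 7) {
  n_out <- input_s / label_res
  if (abs(n_out - round(n_out)) > 1e-9) {
    stop("input_s must be an integer multiple of label_res")
  }
  n_in <- input_s * input_fs
  n_down <- length(encoder_widths) + 1L  # encoder blocks + decoder stage
  if (abs(n_in / 2^n_down - round(n_out)) > 1e-9) {
    stop(sprintf(
      "input length %d cannot reach %d outputs with %d stride-2 stages",
      n_in, round(n_out), n_down))
  }
  structure(list(input_s = input_s, label_res = label_res,
                 input_fs = input_fs, n_in = as.integer(n_in),
                 n_out = as.integer(round(n_out)),
                 encoder_widths = encoder_widths,
                 decoder_width = decoder_width, kernel = kernel),
            class = "sqa_config")
}

#' Training configuration
#'
#' @param batch_size minibatch size (default 256).
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param val_fraction fraction of *subjects* held out for validation; the
#'   split is always by subject identifier, never by segment.
#' @param seed seed for split, shuffling and initial state.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 256, learning_rate = 3e-3,
                         epochs = 40, val_fraction = 0.25, seed = 1L) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop("val_fraction must lie in (0,1)")
  }
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained dense quality model
#'
#' @param cfg an [sqa_config()].
#' @param seed seed for deterministic weight initialisation.
#' @return object of class `sqa_model`; `n_params` reports the parameter
#'   count.
#' @export
build_sqa <- function(cfg = sqa_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sqa_config"))
  layers <- with_seed(seed, {
    widths <- c(1L, cfg$encoder_widths)
    ls <- list()
    for (i in seq_along(cfg$encoder_widths)) {
      ls[[i]] <- nn_conv_layer(widths[i], widths[i + 1L], cfg$kernel, 2L,
                               act = "relu")
    }
    ls[[length(ls) + 1L]] <- nn_conv_layer(
      cfg$encoder_widths[length(cfg$encoder_widths)], cfg$decoder_width,
      cfg$kernel, 2L, act = "relu")
    ls[[length(ls) + 1L]] <- nn_conv_layer(cfg$decoder_width, 1L, 1L, 1L,
                                           act = "linear")
    ls
  })
  structure(list(cfg = cfg, layers = layers,
                 n_params = nn_n_params(layers), trained = FALSE,
                 history = NULL, corpus_fingerprint = NULL),
            class = "sqa_model")
}

#' @export
print.sqa_model <- function(x, ...) {
  cat(sprintf("<sqa_model> %d->%d, %d conv layers, %d parameters, %s\n",
              x$cfg$n_in, x$cfg$n_out, length(x$layers), x$n_params,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# internal: per-segment z-score; a (near-)constant segment maps to zeros
sqa_normalize <- function(m) {
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))
  sdv[sdv < 1e-8] <- 1
  (m - mu) / sdv
}

#' Build a labelled synthetic training corpus
#'
#' Simulates `n_subjects` recordings at the model's internal rate with
#' per-subject physiology and randomised artifact severities (motion
#' bursts, baseline wander, clipping, flatline), then cuts them into
#' non-overlapping 8 s segments with their ground-truth 0.5 s labels.
#'
#' @param n_subjects number of simulated subjects (>= 2).
#' @param duration seconds of signal per subject (default 300).
#' @param cfg an [sqa_config()].
#' @param seed corpus seed.
#' @param kinds artifact kinds to include (default all four); restricting
#'   e.g. to `c("flatline", "clipping")` builds targeted evaluation sets.
#' @return `list(x = segments matrix [n, n_in], y = labels matrix
#'   [n, n_out] (1 = good), subject = integer vector)`.
#' @export
sqa_corpus <- function(n_subjects = 24, duration = 300, cfg = sqa_config(),
                       seed = 1L,
                       kinds = c("motion_burst", "baseline_wander",
                                 "clipping", "flatline")) {
  if (n_subjects < 2) stop("need at least two subjects")
  segs <- list(); labs <- list(); subj <- integer(0)
  n_seg_rec <- floor(duration / cfg$input_s)
  for (s in seq_len(n_subjects)) {
    pars <- with_seed(derive_seed(seed, s), {
      list(hr = stats::runif(1, 55, 95),
           jit = stats::runif(1, 10, 50),
           duty = list(motion = stats::runif(1, 0.05, 0.25),
                       wander = stats::runif(1, 0.05, 0.20),
                       clip = stats::runif(1, 0.02, 0.10),
                       flat = stats::runif(1, 0.02, 0.10)),
           amp = stats::runif(1, 2, 4))
    })
    all_art <- list(
      motion_burst = artifact_spec("motion_burst", pars$duty$motion, 3,
                                   pars$amp),
      baseline_wander = artifact_spec("baseline_wander", pars$duty$wander,
                                      4, 1.8),
      clipping = artifact_spec("clipping", pars$duty$clip, 3, 0.55),
      # sensor-dropout flatlines last tens of seconds, so whole 8 s
      # segments of dropout occur in training, as they do in practice
      flatline = artifact_spec("flatline", pars$duty$flat, 12, 0))
    sp <- simulation_spec(
      mean_hr = pars$hr, jitter_sd = pars$jit, duration = duration,
      fs = cfg$input_fs,
      artifacts = unname(all_art[kinds]),
      seed = derive_seed(seed, s, 1))
    ibi <- generate_ibi_series(sp)
    rec <- render_ppg(ibi, sp$fs, sp$template)
    inj <- inject_artifacts(rec, sp$artifacts,
                            label_res = cfg$label_res,
                            seed = derive_seed(seed, s, 2))
    x <- inj$record$signal
    q <- inj$quality$scores
    n_avail <- min(n_seg_rec, floor(length(x) / cfg$n_in),
                   floor(length(q) / cfg$n_out))
    for (k in seq_len(n_avail)) {
      segs[[length(segs) + 1L]] <-
        x[((k - 1L) * cfg$n_in + 1L):(k * cfg$n_in)]
      labs[[length(labs) + 1L]] <-
        q[((k - 1L) * cfg$n_out + 1L):(k * cfg$n_out)]
      subj <- c(subj, s)
    }
  }
  list(x = do.call(rbind, segs), y = do.call(rbind, labs), subject = subj)
}

#' Train the dense quality model
#'
#' Minimises mean per-0.5 s binary cross-entropy with Adam, with a
#' subject-wise train/validation split (no subject contributes segments to
#' both sides).
#'
#' @param model an [build_sqa()] model.
#' @param corpus a corpus from [sqa_corpus()] (fields `x`, `y`, `subject`).
#' @param tcfg a [train_config()].
#' @return the trained `sqa_model`; `$history` holds per-epoch train loss,
#'   validation loss and validation 0.5 s accuracy, `$val_subjects` the
#'   held-out subject ids.
#' @export
train_sqa <- function(model, corpus, tcfg = train_config()) {
  stopifnot(inherits(model, "sqa_model"))
  subjects <- unique(corpus$subject)
  if (length(subjects) < 2) {
    stop("corpus must contain at least two subjects for a subject-wise split")
  }
  n_val <- max(1L, round(length(subjects) * tcfg$val_fraction))
  val_sub <- with_seed(derive_seed(tcfg$seed, 1),
                       sort(sample(subjects, n_val)))
  is_val <- corpus$subject %in% val_sub
  xtr <- sqa_normalize(corpus$x[!is_val, , drop = FALSE])
  ytr <- corpus$y[!is_val, , drop = FALSE]
  xva <- sqa_normalize(corpus$x[is_val, , drop = FALSE])
  yva <- corpus$y[is_val, , drop = FALSE]

  layers <- model$layers
  state <- nn_adam_init(layers)
  ntr <- nrow(xtr)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0))
  step <- 0L
  for (ep in seq_len(tcfg$epochs)) {
    ord <- with_seed(derive_seed(tcfg$seed, 100 + ep), sample.int(ntr))
    losses <- numeric(0)
    for (b0 in seq(1L, ntr, by = tcfg$batch_size)) {
      bi <- ord[b0:min(ntr, b0 + tcfg$batch_size - 1L)]
      xb <- array(xtr[bi, , drop = FALSE],
                  c(length(bi), ncol(xtr), 1L))
      step <- step + 1L
      st <- nn_train_step(layers, xb, ytr[bi, , drop = FALSE], state,
                          tcfg$learning_rate, step)
      layers <- st$layers; state <- st$state
      losses <- c(losses, st$loss)
    }
    pv <- sqa_forward_matrix(layers, xva)
    val_loss <- nn_bce(pv$logits, yva)
    val_acc <- mean((pv$prob >= 0.5) == (yva >= 0.5), na.rm = TRUE)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_loss = val_loss, val_acc = val_acc))
  }
  model$layers <- layers
  model$trained <- TRUE
  model$history <- hist
  model$val_subjects <- val_sub
  model$corpus_fingerprint <- sprintf(
    "n=%d;n_sub=%d;mean_y=%.6f", nrow(corpus$x),
    length(subjects), mean(corpus$y))
  model
}

# internal: batched forward pass over a matrix of normalised segments
sqa_forward_matrix <- function(layers, xm, batch = 512L) {
  n <- nrow(xm)
  n_out <- NULL
  logits <- NULL
  for (b0 in seq(1L, n, by = batch)) {
    bi <- b0:min(n, b0 + batch - 1L)
    xb <- array(xm[bi, , drop = FALSE], c(length(bi), ncol(xm), 1L))
    out <- nn_forward(layers, xb)$out
    lm <- matrix(out, nrow = length(bi))
    if (is.null(logits)) logits <- matrix(NA_real_, n, ncol(lm))
    logits[bi, ] <- lm
  }
  list(logits = logits, prob = nn_sigmoid(logits))
}

#' Infer quality scores for one 8 s segment
#'
#' The segment must already be at the model's internal rate; it is
#' z-score-normalised internally, so arbitrary gain/offset do not matter.
#'
#' @param model a trained `sqa_model`.
#' @param segment numeric vector of exactly `cfg$n_in` samples, or a
#'   [ppg_record()] of that length at `cfg$input_fs`.
#' @return a [quality_vector()] of `cfg$n_out` scores in `[0,1]`.
#' @export
sqa_infer <- function(model, segment) {
  stopifnot(inherits(model, "sqa_model"))
  if (inherits(segment, "ppg_record")) {
    if (segment$fs != model$cfg$input_fs) {
      segment <- resample_record(segment, model$cfg$input_fs)
    }
    segment <- segment$signal
  }
  if (length(segment) != model$cfg$n_in) {
    stop(sprintf("segment must have %d samples at %g Hz (got %d)",
                 model$cfg$n_in, model$cfg$input_fs, length(segment)))
  }
  xm <- sqa_normalize(matrix(segment, nrow = 1))
  p <- sqa_forward_matrix(model$layers, xm)$prob
  quality_vector(as.numeric(p), res = model$cfg$label_res)
}

#' Annotate a whole recording with quality scores
#'
#' Resamples to the model rate if needed, tiles the record into
#' consecutive 8 s segments and concatenates the per-segment inferences. A
#' trailing partial segment is zero-padded for inference and its padded
#' region left unlabelled (`NA`).
#'
#' @param model a trained `sqa_model`.
#' @param rec a [ppg_record()].
#' @return a [quality_vector()] of `floor(duration / label_res)` entries
#'   aligned to record time.
#' @export
annotate_recording <- function(model, rec) {
  stopifnot(inherits(model, "sqa_model"), inherits(rec, "ppg_record"))
  cfg <- model$cfg
  duration <- record_duration(rec)
  if (rec$fs != cfg$input_fs) rec <- resample_record(rec, cfg$input_fs)
  x <- rec$signal
  n_lab <- floor(duration / cfg$label_res)
  n_full <- floor(length(x) / cfg$n_in)
  n_need <- ceiling(n_lab * cfg$label_res / cfg$input_s)
  segs <- matrix(0, n_need, cfg$n_in)
  for (k in seq_len(n_need)) {
    i0 <- (k - 1L) * cfg$n_in + 1L
    i1 <- min(length(x), k * cfg$n_in)
    if (i0 <= i1) segs[k, seq_len(i1 - i0 + 1L)] <- x[i0:i1]
  }
  if (n_need == 0L) return(quality_vector(numeric(0), res = cfg$label_res))
  p <- sqa_forward_matrix(model$layers, sqa_normalize(segs))$prob
  scores <- as.numeric(t(p))[seq_len(n_lab)]
  # segments fully inside the zero-padded tail are unlabelled
  covered <- floor(length(x) / (cfg$label_res * cfg$input_fs))
  if (covered < n_lab) scores[(covered + 1L):n_lab] <- NA_real_
  quality_vector(scores, res = cfg$label_res)
}

#' Save / load a quality model checkpoint
#'
#' A single-file checkpoint holding the configuration, all parameters, the
#' training history and the corpus fingerprint.
#'
#' @param model an `sqa_model`.
#' @param path checkpoint file path.
#' @return `save_sqa` returns `path` invisibly; `load_sqa` the model.
#' @export
save_sqa <- function(model, path) {
  stopifnot(inherits(model, "sqa_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_sqa
#' @export
load_sqa <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sqa_model")) stop("not an sqa_model checkpoint")
  m
}

#' Dense-model vs pSQI-threshold comparison on artifact detection
#'
#' Evaluates both approaches as binary "bad-segment" detectors at 0.5 s
#' resolution on labelled segments: the model thresholds its per-0.5 s
#' scores at 0.5; the pSQI baseline computes one pSQI per 8 s segment and
#' broadcasts the segment-level decision (pSQI < threshold means bad) to
#' all 16 labels, which is the finest it can do.
#'
#' @param model a trained `sqa_model`.
#' @param x segment matrix (rows of `n_in` samples at `input_fs`).
#' @param y label matrix (1 = good).
#' @param threshold pSQI gate threshold in percent (default 40).
#' @return `data.frame(method, f1, precision, recall, accuracy)` with "bad"
#'   as the positive class.
#' @export
sqa_vs_psqi <- function(model, x, y, threshold = 40) {
  stopifnot(inherits(model, "sqa_model"))
  cfg <- model$cfg
  p <- sqa_forward_matrix(model$layers, sqa_normalize(x))$prob
  pred_bad_model <- p < 0.5
  ps <- apply(x, 1, function(s)
    suppressWarnings(psqi(s, cfg$input_fs)))
  pred_bad_psqi <- matrix(ps < threshold, nrow(y), ncol(y))
  truth_bad <- y < 0.5
  score <- function(pred) {
    tp <- sum(pred & truth_bad); fp <- sum(pred & !truth_bad)
    fn <- sum(!pred & truth_bad)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(f1 = f1, precision = prec, recall = rec,
      accuracy = mean(pred == truth_bad))
  }
  rbind(data.frame(method = "sqa", t(score(pred_bad_model))),
        data.frame(method = "psqi", t(score(pred_bad_psqi))))
}
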