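#' Align two windowed metric series into pairs
#'
#' Pairs are matched on window start time; windows missing (`NA`) in either
#' series are dropped. The two series must share window and step
#' parameters.
#'
#' @param test,ref [windowed_metrics()] series.
#' @return `data.frame(start, test, ref)`; attribute `n_dropped` counts
#'   windows lost to missing values or absent starts.
#' @export
align_pairs <- function(test, ref) {
  stopifnot(inherits(test, "windowed_metrics"),
            inherits(ref, "windowed_metrics"))
  if (!isTRUE(all.equal(attr(test, "window_s"), attr(ref, "window_s"))) ||
      !isTRUE(all.equal(attr(test, "step_s"), attr(ref, "step_s")))) {
    stop("series use different window/step parameters")
  }
  m <- merge(data.frame(start = test$start, test = test$value),
             data.frame(start = ref$start, ref = ref$value),
             by = "start")
  m <- m[order(m$start), ]
  total <- max(nrow(test), nrow(ref))
  keep <- stats::complete.cases(m)
  out <- m[keep, ]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- total - nrow(out)
  out
}

#' Agreement statistics between paired measurements
#'
#' Errors are `test - ref`. RMSE is the root mean square error, MAE the
#' mean absolute error, SD the sample (n-1) standard deviation of the
#' errors and r the sample Pearson correlation between test and reference.
#'
#' @param pairs a data.frame with columns `test` and `ref` (e.g. from
#'   [align_pairs()]).
#' @return `list(n_pairs, rmse, mae, sd_error, pearson_r)`; `pearson_r` is
#'   `NA` (with attribute `r_defined = FALSE`) when either series is
#'   constant.
#' @export
agreement_stats <- function(pairs) {
  x <- pairs$test; y <- pairs$ref
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  e <- x - y
  rmse <- sqrt(sum(e^2) / n)
  mae <- sum(abs(e)) / n
  sd_e <- sqrt(sum((e - sum(e) / n)^2) / (n - 1))
  mx <- sum(x) / n; my <- sum(y) / n
  sxx <- sum((x - mx)^2); syy <- sum((y - my)^2)
  r_defined <- sxx > 0 && syy > 0
  r <- if (r_defined) sum((x - mx) * (y - my)) / sqrt(sxx * syy) else NA_real_
  out <- list(n_pairs = n, rmse = rmse, mae = mae, sd_error = sd_e,
              pearson_r = r)
  attr(out, "r_defined") <- r_defined
  out
}

#' Bland-Altman analysis
#'
#' Bias is the mean of the differences `test - ref`; the limits of
#' agreement are `bias +/- 1.96` sample SDs of the differences. The
#' per-pair `(mean, difference)` table backing the scatter plot is
#' returned alongside.
#'
#' @inheritParams agreement_stats
#' @return `list(bias, loa_low, loa_high, table)` where `table` has
#'   columns `mean` and `diff`.
#' @export
bland_altman <- function(pairs) {
  d <- pairs$test - pairs$ref
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       table = data.frame(mean = (pairs$test + pairs$ref) / 2, diff = d))
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped; tied absolute differences receive
#' mid-ranks. For n <= 15 remaining differences the p-value is exact, by
#' enumerating all 2^n sign assignments of the observed ranks; above that a
#' normal approximation with continuity correction and tie correction is
#' used. W is the sum of ranks of the positive differences.
#'
#' @param x numeric vector (differences, or first sample).
#' @param y optional second sample; then differences are `x - y`.
#' @param alternative `"two.sided"`, `"greater"` (positive shift) or
#'   `"less"`.
#' @param exact_max largest n for exact enumeration (default 15).
#' @return `list(statistic, p_value, n, method, degenerate)`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "greater",
                                                 "less"),
                                 exact_max = 15L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                method = "degenerate", degenerate = TRUE))
  }
  if (n < 5) warning("fewer than 5 non-zero differences: p is coarse")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact distribution of W over all sign assignments of the observed
    # (possibly tied) ranks, by convolution over 2^n assignments
    probs <- 1
    offsets <- 0
    for (ri in r) {
      offsets2 <- c(offsets, offsets + ri)
      probs2 <- c(probs, probs) / 2
      o <- sort(unique(offsets2))
      p <- vapply(o, function(v) sum(probs2[abs(offsets2 - v) < 1e-9]),
                  numeric(1))
      offsets <- o; probs <- p
    }
    p_ge <- sum(probs[offsets >= W - 1e-9])
    p_le <- sum(probs[offsets <= W + 1e-9])
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    method <- "exact sign enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    sigma <- sqrt(sigma2)
    z_g <- (W - mu - 0.5) / sigma
    z_l <- (W - mu + 0.5) / sigma
    p <- switch(alternative,
                greater = stats::pnorm(z_g, lower.tail = FALSE),
                less = stats::pnorm(z_l),
                two.sided = min(1, 2 * min(
                  stats::pnorm(z_g, lower.tail = FALSE),
                  stats::pnorm(z_l))))
    method <- "normal approximation with continuity correction"
  }
  list(statistic = W, p_value = p, n = n, method = method,
       degenerate = FALSE)
}

# internal: full analysis of one simulated session; returns aligned pairs
# per metric plus mean device pSQI
analyze_session <- function(sess, fp = filter_params(),
                            bp_detect = beat_detector_params(),
                            hr_wp = window_params(30, 10),
                            prv_wp = window_params(120, 10),
                            gate_threshold = 40) {
  pipe <- function(rec) {
    f <- bandpass(rec, fp)
    b <- detect_beats(f, bp_detect)
    ibi_from_beats(b, rec$fs, duration = record_duration(rec))
  }
  ibi_dev <- pipe(sess$device)
  ibi_ref <- pipe(sess$reference)
  hr_pairs <- {
    g <- quality_gate(hr_windowed(ibi_dev, hr_wp),
                      hr_windowed(ibi_ref, hr_wp),
                      sess$reference, threshold = gate_threshold)
    align_pairs(g$test, g$ref)
  }
  prv_pairs <- {
    g <- quality_gate(prv_windowed(ibi_dev, prv_wp),
                      prv_windowed(ibi_ref, prv_wp),
                      sess$reference, threshold = gate_threshold)
    align_pairs(g$test, g$ref)
  }
  psqi_dev <- mean(psqi_windowed(sess$device, hr_wp)$value, na.rm = TRUE)
  list(hr = hr_pairs, prv = prv_pairs, psqi_device = psqi_dev)
}

#' Per-condition device-agreement report for a simulated study
#'
#' Runs the full pipeline (band-pass, beat detection, windowed HR and
#' pNN50, paired pSQI gating against the reference record) on every
#' session, pools gated windows across subjects within each condition, and
#' reports agreement statistics per metric and condition plus an
#' "all sessions combined" row. Mean device-channel pSQI per condition is
#' reported alongside.
#'
#' @param study a `ppg_study` from [simulate_study()].
#' @param gate_threshold reference pSQI gate in percent (default 40).
#' @param fp a [filter_params()].
#' @return `list(table, psqi, pairs)`: `table` is a data.frame keyed by
#'   metric and condition with columns `n_pairs, rmse, mae, sd_error,
#'   pearson_r, bias, loa_low, loa_high`; `psqi` holds mean device pSQI
#'   per condition; `pairs` the pooled pairs per metric and condition.
#' @export
condition_report <- function(study, gate_threshold = 40,
                             fp = filter_params()) {
  stopifnot(inherits(study, "ppg_study"))
  conditions <- names(study$protocol$conditions)
  pools <- list(hr = list(), prv = list())
  psqi_by_cond <- stats::setNames(vector("list", length(conditions)),
                                  conditions)
  for (sess in study$sessions) {
    res <- analyze_session(sess, fp = fp, gate_threshold = gate_threshold)
    for (m in c("hr", "prv")) {
      pools[[m]][[sess$condition]] <-
        rbind(pools[[m]][[sess$condition]], res[[m]])
    }
    psqi_by_cond[[sess$condition]] <-
      c(psqi_by_cond[[sess$condition]], res$psqi_device)
  }
  rows <- list()
  pairs_out <- list()
  for (m in c("hr", "prv")) {
    metric <- if (m == "hr") "hr_bpm" else "pnn50_pct"
    all_pairs <- do.call(rbind, pools[[m]])
    for (cond in c(conditions, "combined")) {
      pr <- if (cond == "combined") all_pairs else pools[[m]][[cond]]
      pairs_out[[paste(m, cond, sep = ".")]] <- pr
      if (is.null(pr) || nrow(pr) < 3) next
      st <- agreement_stats(pr)
      ba <- bland_altman(pr)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = metric, condition = cond, n_pairs = st$n_pairs,
        rmse = st$rmse, mae = st$mae, sd_error = st$sd_error,
        pearson_r = st$pearson_r, bias = ba$bias,
        loa_low = ba$loa_low, loa_high = ba$loa_high)
    }
  }
  list(table = do.call(rbind, rows),
       psqi = data.frame(condition = conditions,
                         mean_psqi = vapply(psqi_by_cond,
                                            function(v) mean(unlist(v)),
                                            numeric(1))),
       pairs = pairs_out)
}

#' Batch analysis of a session directory
#'
#' Discovers session CSVs via `manifest.json`, runs the
#' preprocess/metrics pipeline on each device recording, and writes a
#' summary spreadsheet (`summary.csv`) plus a keyed archive
#' (`summary.rds`, a named list keyed by `participant.condition.metric`).
#' Per-file failures are logged and the batch continues.
#'
#' @param session_dir directory containing `manifest.json` and session
#'   CSVs (see [write_study()]).
#' @param config analysis configuration: a list (or path to a JSON file)
#'   with fields `fs`, `window_s`, `step_s`, `metrics` (subset of
#'   `"hr"`, `"pnn50"`, `"psqi"`).
#' @param out_dir output directory (defaults to `session_dir`).
#' @return `list(summary, errors)`; `summary` is the table written to
#'   `summary.csv`.
#' @export
analyze_batch <- function(session_dir, config = list(), out_dir = session_dir) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- utils::modifyList(
    list(window_s = 30, step_s = 10, metrics = c("hr", "pnn50", "psqi"),
         prv_window_s = 120), config)
  man_path <- file.path(session_dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", session_dir)
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  rows <- list(); archive <- list(); errors <- character(0)
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, ]
    res <- tryCatch({
      sess <- read_session(file.path(session_dir, entry$device))
      ch <- names(sess$channels)[1]
      rec <- ppg_record(sess$channels[[ch]], sess$meta$fs, channel = ch)
      f <- bandpass(rec)
      ibi <- ibi_from_beats(detect_beats(f), rec$fs,
                            duration = record_duration(rec))
      out <- list()
      if ("hr" %in% cfg$metrics) {
        out$hr <- hr_windowed(ibi, window_params(cfg$window_s, cfg$step_s))
      }
      if ("pnn50" %in% cfg$metrics) {
        out$pnn50 <- prv_windowed(ibi, window_params(cfg$prv_window_s,
                                                     cfg$step_s))
      }
      if ("psqi" %in% cfg$metrics) {
        out$psqi <- psqi_windowed(rec, window_params(cfg$window_s,
                                                     cfg$step_s))
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("%s: %s", entry$device,
                                  conditionMessage(res)))
      next
    }
    for (mn in names(res)) {
      key <- sprintf("sub%02d.%s.%s", entry$subject, entry$condition, mn)
      archive[[key]] <- as.data.frame(res[[mn]])
      rows[[length(rows) + 1L]] <- data.frame(
        participant = sprintf("sub%02d", entry$subject),
        condition = entry$condition, metric = mn,
        n_windows = nrow(res[[mn]]),
        mean = mean(res[[mn]]$value, na.rm = TRUE),
        sd = stats::sd(res[[mn]]$value, na.rm = TRUE))
    }
  }
  summary <- do.call(rbind, rows)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  saveRDS(archive, file.path(out_dir, "summary.rds"))
  if (length(errors)) {
    writeLines(errors, file.path(out_dir, "errors.log"))
  }
  list(summary = summary, errors = errors)
}
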