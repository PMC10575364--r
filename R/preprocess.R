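#' Band-pass filter parameters
#'
#' Defaults follow the standard PPG pulse band: 0.7-4.0 Hz, third order.
#' The filter family is Butterworth, applied forward-backward
#' (`zero_phase = TRUE`) so that peak times are not shifted; "order" is the
#' designed order of the one-directional prototype, and the effective
#' magnitude response of the bidirectional pass is its square.
#'
#' @param low_cut lower passband edge, Hz.
#' @param high_cut upper passband edge, Hz.
#' @param order designed filter order (>= 1).
#' @param zero_phase apply forward-backward (filtfilt)?
#' @return object of class `filter_params`.
#' @export
filter_params <- function(low_cut = 0.7, high_cut = 4.0, order = 3,
                          zero_phase = TRUE) {
  if (low_cut <= 0 || high_cut <= low_cut) {
    stop("need 0 < low_cut < high_cut")
  }
  if (order < 1) stop("order must be >= 1")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 order = as.integer(order), zero_phase = zero_phase),
            class = "filter_params")
}

#' Band-pass filter a PPG record
#'
#' Butterworth band-pass; zero-phase by default. Length and sampling rate
#' are preserved.
#'
#' @param rec a [ppg_record()].
#' @param p a [filter_params()].
#' @return filtered [ppg_record()].
#' @export
bandpass <- function(rec, p = filter_params()) {
  stopifnot(inherits(rec, "ppg_record"), inherits(p, "filter_params"))
  if (rec$fs <= 2 * p$high_cut) {
    stop(sprintf("sampling rate %g Hz too low for high_cut %g Hz",
                 rec$fs, p$high_cut))
  }
  bw <- signal::butter(p$order, c(p$low_cut, p$high_cut) / (rec$fs / 2),
                       type = "pass")
  y <- if (p$zero_phase) signal::filtfilt(bw, rec$signal)
       else as.numeric(signal::filter(bw, rec$signal))
  out <- ppg_record(y, rec$fs, channel = rec$channel, quality = rec$quality)
  for (a in c("peak_times")) attr(out, a) <- attr(rec, a)
  out
}

#' Sliding-window parameters
#'
#' @param window_s window length in seconds (> 0).
#' @param step_s step between window starts in seconds (0 < step <= window).
#' @return object of class `window_params`.
#' @export
window_params <- function(window_s, step_s) {
  if (window_s <= 0) stop("window_s must be > 0")
  if (step_s <= 0 || step_s > window_s) {
    stop("need 0 < step_s <= window_s")
  }
  structure(list(window_s = window_s, step_s = step_s),
            class = "window_params")
}

#' Enumerate complete sliding windows
#'
#' Window k covers the half-open span `[k*step_s, k*step_s + window_s)`;
#' only complete windows are emitted, so a record of duration `T` yields
#' `floor((T - window_s)/step_s) + 1` windows for `T >= window_s` and none
#' otherwise.
#'
#' @param x a [ppg_record()], [ibi_series()] or a duration in seconds.
#' @param p a [window_params()].
#' @return `data.frame(start, end)` of window spans in seconds (possibly
#'   zero rows).
#' @export
window_iter <- function(x, p) {
  stopifnot(inherits(p, "window_params"))
  T <- if (inherits(x, "ppg_record")) record_duration(x)
       else if (inherits(x, "ibi_series")) x$duration
       else as.numeric(x)
  if (T < p$window_s) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  k <- 0:floor((T - p$window_s) / p$step_s)
  data.frame(start = k * p$step_s, end = k * p$step_s + p$window_s)
}

#' Resample a record to a new rate
#'
#' Band-limited polyphase resampling; duration is preserved to within one
#' sample of the target rate.
#'
#' @param rec a [ppg_record()].
#' @param target_fs new sampling rate in Hz (>= 25).
#' @return resampled [ppg_record()].
#' @export
resample_record <- function(rec, target_fs) {
  stopifnot(inherits(rec, "ppg_record"))
  if (!is.numeric(target_fs) || target_fs < 25) {
    stop("target_fs must be >= 25 Hz")
  }
  if (target_fs == rec$fs) return(rec)
  r <- target_fs / rec$fs
  fr <- rational_approx(r)
  y <- signal::resample(rec$signal, fr[1], fr[2])
  n_target <- round(length(rec$signal) * r)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, rep(y[length(y)], n_target - length(y)))
  ppg_record(y, target_fs, channel = rec$channel)
}

# internal: small-denominator rational approximation p/q of a ratio
rational_approx <- function(r, max_den = 4096) {
  best <- c(1, 1); err <- Inf
  for (q in 1:max_den) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(r - p / q)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  best
}

#' Apply a metric to every complete window of a sample vector
#'
#' Offline counterpart of [stream_engine()]: slices the record into
#' complete windows and applies `metric_fn(samples, fs)` to each.
#'
#' @param rec a [ppg_record()].
#' @param metric_fn function of `(samples, fs)` returning a scalar.
#' @param p a [window_params()].
#' @param metric metric name for the result.
#' @return a [windowed_metrics()] series.
#' @export
window_apply <- function(rec, metric_fn, p, metric = "metric") {
  stopifnot(inherits(rec, "ppg_record"))
  w <- window_iter(rec, p)
  vals <- vapply(seq_len(nrow(w)), function(k) {
    i0 <- round(w$start[k] * rec$fs) + 1L
    i1 <- round(w$end[k] * rec$fs)
    as.numeric(metric_fn(rec$signal[i0:i1], rec$fs))
  }, numeric(1))
  windowed_metrics(w$start, vals, p$window_s, p$step_s, metric = metric)
}
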