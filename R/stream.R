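#' Synthetic sample source emulating a device stream
#'
#' Replays a session file, a plain numeric vector or a live simulation as a
#' pull-based iterator of integer ADC-like values; stands in for serial
#' hardware. By default it replays as fast as the consumer pulls
#' (`realtime = FALSE`); with `realtime = TRUE` it sleeps to the nominal
#' rate.
#'
#' @param x a session CSV path, a numeric vector, a [ppg_record()], or a
#'   [simulation_spec()] (simulated, rendered and quantised on the fly).
#' @param fs nominal sampling rate; taken from the input where available.
#'   A mismatch between this and the input's own rate emits a warning.
#' @param channel channel to replay when `x` is a session file.
#' @param realtime sleep to the nominal rate between chunks?
#' @return a function `source(n)` returning up to `n` samples, or `NULL`
#'   when exhausted; attributes `fs` and `n_total` describe the stream.
#' @export
synthetic_serial_source <- function(x, fs = NULL, channel = NULL,
                                    realtime = FALSE) {
  native_fs <- NULL
  if (inherits(x, "simulation_spec")) {
    rec <- render_ppg(generate_ibi_series(x), x$fs, x$template)
    samples <- adc_quantize(rec$signal)
    native_fs <- x$fs
  } else if (inherits(x, "ppg_record")) {
    samples <- adc_quantize(x$signal)
    native_fs <- x$fs
  } else if (is.character(x)) {
    sess <- read_session(x)
    ch <- if (is.null(channel)) names(sess$channels)[1] else channel
    samples <- as.numeric(sess$channels[[ch]])
    native_fs <- sess$meta$fs
  } else {
    samples <- as.numeric(x)
  }
  if (is.null(fs)) fs <- native_fs
  if (is.null(fs)) stop("`fs` required when the input carries no rate")
  if (!is.null(native_fs) && !isTRUE(all.equal(fs, native_fs))) {
    warning(sprintf("requested fs %g Hz differs from source fs %g Hz",
                    fs, native_fs))
  }
  pos <- 0L
  n_total <- length(samples)
  src <- function(n = 1L) {
    if (pos >= n_total) return(NULL)
    take <- min(n, n_total - pos)
    out <- samples[(pos + 1L):(pos + take)]
    pos <<- pos + take
    if (realtime) Sys.sleep(take / fs)
    out
  }
  attr(src, "fs") <- fs
  attr(src, "n_total") <- n_total
  src
}

#' Real-time sliding-window metric stream
#'
#' Pulls samples from a source and emits one metric value per step once
#' the first full window has been seen; emitted values are identical to
#' offline windowing of the same samples (see [window_apply()]). A starved
#' source simply ends the stream early — no values are fabricated.
#'
#' @param source a sample iterator as returned by
#'   [synthetic_serial_source()] (a function of `n`, with an `fs`
#'   attribute), or a plain function of `n` if `fs` is given.
#' @param metric_fn function of `(samples, fs)` applied to each trailing
#'   window.
#' @param window_s,step_s window length and step in seconds
#'   (`window_s >= step_s`).
#' @param fs sampling rate; defaults to the source's `fs` attribute.
#' @param on_value optional callback invoked as `on_value(start, value)`
#'   at each emission (for live biofeedback).
#' @param chunk samples pulled per iteration.
#' @return [windowed_metrics()] of the emitted values.
#' @export
stream_engine <- function(source, metric_fn, window_s, step_s, fs = NULL,
                          on_value = NULL, chunk = 32L) {
  if (is.null(fs)) fs <- attr(source, "fs")
  if (is.null(fs)) stop("`fs` must be supplied or carried by the source")
  if (step_s > window_s) stop("window_s must be >= step_s")
  n_win <- round(window_s * fs)
  n_step <- round(step_s * fs)
  buf <- numeric(0)
  emitted_start <- numeric(0)
  emitted_val <- numeric(0)
  next_end <- n_win
  repeat {
    got <- source(chunk)
    if (is.null(got)) break
    buf <- c(buf, got)
    while (length(buf) >= next_end) {
      seg <- buf[(next_end - n_win + 1L):next_end]
      v <- as.numeric(metric_fn(seg, fs))
      st <- (next_end - n_win) / fs
      emitted_start <- c(emitted_start, st)
      emitted_val <- c(emitted_val, v)
      if (!is.null(on_value)) on_value(st, v)
      next_end <- next_end + n_step
    }
  }
  windowed_metrics(emitted_start, emitted_val, window_s, step_s,
                   metric = "stream")
}

#' Map a metric value to a normalized biofeedback scalar
#'
#' Linear map of `[min, max]` onto `[0, 1]`, clamped at both ends; the
#' scalar drives an external visual property (size, colour). `NA` in gives
#' `NA` out.
#'
#' @param value metric value(s).
#' @param min,max metric range mapped to 0 and 1 (`min < max`).
#' @return numeric in `[0, 1]` (vectorised).
#' @export
biofeedback_map <- function(value, min, max) {
  if (min >= max) stop("min must be < max")
  pmin(1, pmax(0, (value - min) / (max - min)))
}
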