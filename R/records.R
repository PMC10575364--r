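#' Uniformly sampled PPG recording
#'
#' The basic signal container: a numeric vector sampled at a fixed rate, with
#' a channel name and an optional per-0.5 s quality annotation attached.
#'
#' @param signal numeric vector of samples (arbitrary units).
#' @param fs sampling rate in Hz (>= 25).
#' @param channel channel name, e.g. `"ppg_finger"`.
#' @param quality optional [quality_vector()] aligned to the record.
#' @return An object of class `ppg_record` with fields `signal`, `fs`,
#'   `channel`, `quality` and a `duration()` given by `length(signal)/fs`.
#' @export
ppg_record <- function(signal, fs, channel = "ppg", quality = NULL) {
  if (!is.numeric(signal)) stop("`signal` must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs < 25) {
    stop("`fs` must be a single number >= 25 Hz")
  }
  if (!is.null(quality) && !inherits(quality, "quality_vector")) {
    stop("`quality` must be a quality_vector or NULL")
  }
  structure(
    list(signal = as.numeric(signal), fs = fs, channel = channel,
         quality = quality),
    class = "ppg_record"
  )
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record> channel=%s fs=%g Hz n=%d (%.1f s)%s\n",
              x$channel, x$fs, length(x$signal),
              length(x$signal) / x$fs,
              if (is.null(x$quality)) "" else " [annotated]"))
  invisible(x)
}

#' Duration of a record in seconds
#' @param rec a `ppg_record`.
#' @return seconds.
#' @export
record_duration <- function(rec) length(rec$signal) / rec$fs

#' Ordered inter-beat-interval series
#'
#' Intervals in milliseconds together with the timestamp (seconds) of the
#' *second* beat of each interval; window membership of an interval is
#' decided by that timestamp. An optional `duration` attribute carries the
#' length of the originating record so that windowing past the last beat is
#' well defined.
#'
#' @param intervals inter-beat intervals in ms.
#' @param times timestamps (s) of the second beat of each interval.
#' @param duration optional total duration (s) of the underlying recording.
#' @param flagged logical vector marking intervals discarded by plausibility
#'   screening (kept for bookkeeping; flagged intervals are excluded from
#'   metric computation).
#' @return An object of class `ibi_series`.
#' @export
ibi_series <- function(intervals, times, duration = NULL, flagged = NULL) {
  intervals <- as.numeric(intervals)
  times <- as.numeric(times)
  if (length(intervals) != length(times)) {
    stop("`intervals` and `times` must have equal length")
  }
  if (is.unsorted(times)) stop("`times` must be non-decreasing")
  if (is.null(flagged)) flagged <- rep(FALSE, length(intervals))
  structure(
    list(intervals = intervals, times = times,
         duration = if (is.null(duration)) max(times, 0) else duration,
         flagged = as.logical(flagged)),
    class = "ibi_series"
  )
}

#' @export
print.ibi_series <- function(x, ...) {
  n <- length(x$intervals)
  cat(sprintf("<ibi_series> n=%d duration=%.1f s mean IBI=%.1f ms (%d flagged)\n",
              n, x$duration, if (n) mean(x$intervals[!x$flagged]) else NA_real_,
              sum(x$flagged)))
  invisible(x)
}

#' @export
length.ibi_series <- function(x) length(x$intervals)

#' Binary / scored quality labels at fixed temporal resolution
#'
#' One value per `res`-second segment; 1 means clean ("good"), 0 means
#' corrupted ("bad"). Scores in between arise from model inference and are
#' binarised at 0.5 by [quality_binary()]. `NA` marks unlabelled segments
#' (e.g. zero-padded tails).
#'
#' @param scores numeric vector in `[0,1]` (or `NA`).
#' @param res label resolution in seconds (default 0.5).
#' @param offset alignment offset in seconds relative to record start.
#' @return An object of class `quality_vector`.
#' @export
quality_vector <- function(scores, res = 0.5, offset = 0) {
  scores <- as.numeric(scores)
  ok <- is.na(scores) | (scores >= 0 & scores <= 1)
  if (!all(ok)) stop("quality scores must lie in [0,1] or be NA")
  structure(list(scores = scores, res = res, offset = offset),
            class = "quality_vector")
}

#' Binary view of a quality vector
#' @param q a `quality_vector`.
#' @param threshold score threshold for "good" (default 0.5).
#' @return logical vector, `TRUE` = good, `NA` preserved.
#' @export
quality_binary <- function(q, threshold = 0.5) {
  stopifnot(inherits(q, "quality_vector"))
  ifelse(is.na(q$scores), NA, q$scores >= threshold)
}

#' @export
print.quality_vector <- function(x, ...) {
  b <- quality_binary(x)
  cat(sprintf("<quality_vector> n=%d res=%.2g s good=%d bad=%d unlabelled=%d\n",
              length(x$scores), x$res, sum(b, na.rm = TRUE),
              sum(!b, na.rm = TRUE), sum(is.na(b))))
  invisible(x)
}

#' @export
length.quality_vector <- function(x) length(x$scores)

#' Windowed metric series
#'
#' Metric values (e.g. HR in bpm or pNN50 in %) evaluated on sliding
#' windows, keyed by window start time, with window/step provenance kept as
#' attributes so that two series can be checked for grid compatibility.
#'
#' @param start window start times in seconds.
#' @param value metric values (`NA` where the window had too little data).
#' @param window_s,step_s windowing parameters used.
#' @param metric metric name.
#' @return A `data.frame` of class `windowed_metrics` with columns
#'   `start`, `value`.
#' @export
windowed_metrics <- function(start, value, window_s, step_s, metric = "metric") {
  out <- data.frame(start = as.numeric(start), value = as.numeric(value))
  attr(out, "window_s") <- window_s
  attr(out, "step_s") <- step_s
  attr(out, "metric") <- metric
  class(out) <- c("windowed_metrics", "data.frame")
  out
}

#' @export
print.windowed_metrics <- function(x, ...) {
  cat(sprintf("<windowed_metrics> %s, window=%g s step=%g s, %d windows (%d NA)\n",
              attr(x, "metric"), attr(x, "window_s"), attr(x, "step_s"),
              nrow(x), sum(is.na(x$value))))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}

# internal: evaluate an expression with a temporary RNG state seeded at
# `seed`, restoring the caller's state afterwards so library functions do
# not clobber user RNG streams.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# internal: derive a bounded child seed from a base seed and stream labels
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 1000003 + as.numeric(p) + 7) %% 2147483629
  as.integer(s)
}
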