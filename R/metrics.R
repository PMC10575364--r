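#' Beat-detector parameters
#'
#' @param min_ibi_ms refractory period in ms; no two detections closer than
#'   this (default 330 ms, a 180 bpm cap). Must be >= 250.
#' @param prominence_fraction candidate peaks must rise above the rolling
#'   minimum by at least this fraction of the rolling amplitude.
#' @param rolling_window_s span of the rolling amplitude estimate, seconds.
#' @return object of class `beat_detector_params`.
#' @export
beat_detector_params <- function(min_ibi_ms = 330, prominence_fraction = 0.3,
                                 rolling_window_s = 2) {
  if (min_ibi_ms < 250) stop("min_ibi_ms must be >= 250")
  if (prominence_fraction <= 0 || prominence_fraction >= 1) {
    stop("prominence_fraction must lie in (0,1)")
  }
  structure(list(min_ibi_ms = min_ibi_ms,
                 prominence_fraction = prominence_fraction,
                 rolling_window_s = rolling_window_s),
            class = "beat_detector_params")
}

#' Healthy-range screen for derived metrics
#'
#' Intervals and metric values outside these ranges are treated as
#' implausible and discarded (flagged). Defaults cover the normal healthy
#' range; all bounds are configurable.
#'
#' @param hr heart-rate range, bpm.
#' @param pnn50 pNN50 range, percent.
#' @param ibi inter-beat-interval range, ms.
#' @return object of class `healthy_range`.
#' @export
healthy_range <- function(hr = c(40, 200), pnn50 = c(0, 100),
                          ibi = c(250, 2000)) {
  for (r in list(hr, pnn50, ibi)) {
    if (length(r) != 2 || r[1] >= r[2]) stop("each range must be (lower, upper)")
  }
  structure(list(hr = hr, pnn50 = pnn50, ibi = ibi), class = "healthy_range")
}

# internal: centered rolling max/min with edge padding
roll_extreme <- function(x, k, max = TRUE) {
  k <- max(3L, as.integer(k))
  if (k %% 2 == 0) k <- k + 1L
  v <- if (max) zoo::rollmax(x, k, fill = NA, align = "center")
       else -zoo::rollmax(-x, k, fill = NA, align = "center")
  h <- (k - 1L) %/% 2L
  v[seq_len(h)] <- v[h + 1L]
  v[(length(x) - h + 1L):length(x)] <- v[length(x) - h]
  v
}

#' Detect systolic peaks in a filtered PPG record
#'
#' Local maxima exceeding an adaptive prominence threshold (a fraction of
#' the rolling signal amplitude above the rolling minimum), thinned by a
#' refractory period: within `min_ibi_ms` the taller peak wins and the
#' earlier wins on an exact tie. Deterministic. Sub-sample peak times from
#' a parabolic fit around each maximum are attached as attribute
#' `times` (seconds).
#'
#' @param rec a band-passed [ppg_record()].
#' @param p a [beat_detector_params()].
#' @return integer vector of beat sample indices (1-based), with attribute
#'   `times` giving refined peak times in seconds.
#' @export
detect_beats <- function(rec, p = beat_detector_params()) {
  stopifnot(inherits(rec, "ppg_record"))
  x <- rec$signal
  n <- length(x)
  if (n < 3 || max(x) == min(x)) {
    out <- integer(0); attr(out, "times") <- numeric(0); return(out)
  }
  k <- round(p$rolling_window_s * rec$fs)
  rmax <- roll_extreme(x, k, max = TRUE)
  rmin <- roll_extreme(x, k, max = FALSE)
  amp <- rmax - rmin
  thr <- rmin + p$prominence_fraction * amp
  # strict rise from the left, non-strict to the right: plateau/tie keeps
  # the earliest sample
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= thr[cand] & amp[cand] > 1e-12]
  if (!length(cand)) {
    out <- integer(0); attr(out, "times") <- numeric(0); return(out)
  }
  refrac <- p$min_ibi_ms / 1000 * rec$fs
  kept <- integer(0)
  for (i in cand) {
    if (!length(kept) || (i - kept[length(kept)]) >= refrac) {
      kept <- c(kept, i)
    } else if (x[i] > x[kept[length(kept)]]) {
      kept[length(kept)] <- i   # taller peak replaces within refractory
    }
  }
  times <- (kept - 1) / rec$fs
  # parabolic refinement on interior peaks
  ok <- kept > 1L & kept < n
  i <- kept[ok]
  denom <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  d <- ifelse(abs(denom) > 1e-12,
              0.5 * (x[i - 1L] - x[i + 1L]) / denom, 0)
  d[abs(d) > 0.5] <- 0
  times[ok] <- times[ok] + d / rec$fs
  attr(kept, "times") <- times
  kept
}

#' Interval series from detected beats
#'
#' Successive differences of beat times in ms; intervals outside the
#' healthy IBI range are discarded and flagged, with timestamps preserved
#' so that later windowing can respect the gaps they leave.
#'
#' @param beats beat sample indices as returned by [detect_beats()] (an
#'   attached `times` attribute, if present, takes precedence over the
#'   integer indices).
#' @param fs sampling rate in Hz.
#' @param range a [healthy_range()].
#' @param duration optional total record duration in seconds.
#' @return an [ibi_series()] containing only plausible intervals; the
#'   number discarded is available as attribute `n_discarded`.
#' @export
ibi_from_beats <- function(beats, fs, range = healthy_range(),
                           duration = NULL) {
  times <- attr(beats, "times")
  if (is.null(times)) times <- (as.numeric(beats) - 1) / fs
  if (length(times) < 2) {
    out <- ibi_series(numeric(0), numeric(0), duration = duration)
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  iv <- diff(times) * 1000
  tt <- times[-1]
  keep <- iv >= range$ibi[1] & iv <= range$ibi[2]
  out <- ibi_series(iv[keep], tt[keep], duration = duration)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

# internal: which retained intervals are adjacent to their predecessor
# (the first beat of interval i is the second beat of interval i-1)
adjacent_pairs <- function(ibi, tol = 1e-6) {
  n <- length(ibi$intervals)
  if (n < 2) return(logical(0))
  start_of <- ibi$times - ibi$intervals / 1000
  abs(start_of[-1] - ibi$times[-n]) < tol
}

#' Windowed heart rate
#'
#' Per window, HR = 60000 / mean(intervals whose second-beat time falls in
#' the window); windows with fewer than two usable intervals yield `NA`.
#'
#' @param ibi an [ibi_series()].
#' @param p a [window_params()] (default 30 s window, 10 s step).
#' @param duration total duration in seconds; defaults to the series'
#'   `duration` field.
#' @return [windowed_metrics()] of HR in bpm.
#' @export
hr_windowed <- function(ibi, p = window_params(30, 10), duration = NULL) {
  stopifnot(inherits(ibi, "ibi_series"))
  if (is.null(duration)) duration <- ibi$duration
  w <- window_iter(duration, p)
  iv <- ibi$intervals[!ibi$flagged]
  tt <- ibi$times[!ibi$flagged]
  vals <- vapply(seq_len(nrow(w)), function(k) {
    sel <- tt >= w$start[k] & tt < w$end[k]
    if (sum(sel) < 2) return(NA_real_)
    60000 / mean(iv[sel])
  }, numeric(1))
  windowed_metrics(w$start, vals, p$window_s, p$step_s, metric = "hr_bpm")
}

#' pNN50: proportion of large successive interval differences
#'
#' 100 times the fraction of successive inter-beat-interval differences
#' whose absolute value strictly exceeds 50 ms. Differences are only formed
#' between intervals that are adjacent in the beat sequence (gaps left by
#' discarded intervals break the chain). Fewer than two successive
#' differences give `NA`, not zero.
#'
#' @param ibi an [ibi_series()], or a plain numeric vector of intervals
#'   in ms (assumed consecutive).
#' @param threshold_ms difference threshold (default 50 ms, strict).
#' @return pNN50 in percent, or `NA_real_`.
#' @export
pnn50 <- function(ibi, threshold_ms = 50) {
  if (inherits(ibi, "ibi_series")) {
    keep <- !ibi$flagged
    sub <- ibi_series(ibi$intervals[keep], ibi$times[keep],
                      duration = ibi$duration)
    d <- diff(sub$intervals)[adjacent_pairs(sub, tol = 1e-6)]
  } else {
    d <- diff(as.numeric(ibi))
  }
  if (length(d) < 2) return(NA_real_)
  100 * sum(abs(d) > threshold_ms) / length(d)
}

#' Windowed pulse-rate variability (pNN50)
#'
#' pNN50 per sliding window (default 120 s window, 10 s step). An interval
#' difference belongs to the window containing the second interval's beat
#' time. Windows with fewer than two usable differences give `NA`.
#'
#' @inheritParams hr_windowed
#' @param p a [window_params()] (default 120 s / 10 s).
#' @return [windowed_metrics()] of pNN50 in percent.
#' @export
prv_windowed <- function(ibi, p = window_params(120, 10), duration = NULL) {
  stopifnot(inherits(ibi, "ibi_series"))
  if (is.null(duration)) duration <- ibi$duration
  w <- window_iter(duration, p)
  keep <- !ibi$flagged
  sub <- ibi_series(ibi$intervals[keep], ibi$times[keep],
                    duration = ibi$duration)
  n <- length(sub$intervals)
  if (n >= 2) {
    adj <- adjacent_pairs(sub)
    d <- diff(sub$intervals)[adj]
    dt <- sub$times[-1][adj]
  } else {
    d <- numeric(0); dt <- numeric(0)
  }
  vals <- vapply(seq_len(nrow(w)), function(k) {
    sel <- dt >= w$start[k] & dt < w$end[k]
    if (sum(sel) < 2) return(NA_real_)
    100 * sum(abs(d[sel]) > 50) / sum(sel)
  }, numeric(1))
  windowed_metrics(w$start, vals, p$window_s, p$step_s, metric = "pnn50_pct")
}
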