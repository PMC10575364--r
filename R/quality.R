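#' pSQI parameters
#'
#' The relative power signal quality index compares spectral power in the
#' pulse band with total power. The pulse band defaults to the 0.7-4.0 Hz
#' passband used for filtering; the total band spans (0, 10] Hz (the mean
#' is removed, so the DC bin never contributes).
#'
#' @param pulse_band numeric length-2, Hz.
#' @param total_band numeric length-2, Hz; must contain `pulse_band`.
#' @return object of class `psqi_params`.
#' @export
psqi_params <- function(pulse_band = c(0.7, 4.0), total_band = c(0, 10)) {
  if (pulse_band[1] < total_band[1] || pulse_band[2] > total_band[2]) {
    stop("pulse_band must lie within total_band")
  }
  structure(list(pulse_band = pulse_band, total_band = total_band),
            class = "psqi_params")
}

#' Relative power signal quality index
#'
#' 100 times the ratio of periodogram power in the pulse band to power in
#' the total band, computed on the mean-removed segment with a single
#' full-length periodogram (so the value equals a direct FFT band-power
#' summation). A constant segment has no power and is defined as 0% with a
#' warning; segments shorter than 10 s give a coarse frequency grid and
#' also warn.
#'
#' @param x numeric segment, or a [ppg_record()] (then `fs` is taken from
#'   it).
#' @param fs sampling rate in Hz (ignored when `x` is a record).
#' @param p a [psqi_params()].
#' @return pSQI in percent, in `[0, 100]`.
#' @export
psqi <- function(x, fs = NULL, p = psqi_params()) {
  if (inherits(x, "ppg_record")) { fs <- x$fs; x <- x$signal }
  if (is.null(fs)) stop("`fs` required for a plain numeric segment")
  if (p$total_band[2] >= fs / 2) {
    stop("total band upper edge must be below fs/2")
  }
  n <- length(x)
  if (n / fs < 10) warning("segment shorter than 10 s; pSQI estimate is coarse")
  x <- x - mean(x)
  if (stats::sd(x) < 1e-12) {
    warning("constant segment: pSQI defined as 0%")
    return(0)
  }
  pw <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  half <- freq <= fs / 2
  pw <- pw[half]; freq <- freq[half]
  inb <- function(b) freq > max(b[1], 0) - 1e-12 & freq <= b[2] + 1e-12
  tot <- sum(pw[inb(p$total_band) & freq > 1e-12])
  pul <- sum(pw[inb(p$pulse_band)])
  if (tot <= 0) return(0)
  100 * min(1, pul / tot)
}

#' pSQI over a sliding-window grid
#'
#' @param rec a [ppg_record()] (typically the raw, unfiltered signal).
#' @param wp a [window_params()].
#' @param p a [psqi_params()].
#' @return [windowed_metrics()] of pSQI in percent.
#' @export
psqi_windowed <- function(rec, wp, p = psqi_params()) {
  out <- suppressWarnings(
    window_apply(rec, function(x, fs) psqi(x, fs, p), wp, metric = "psqi_pct"))
  out
}

#' Paired quality gating at a reference pSQI threshold
#'
#' Windows whose *reference-record* pSQI falls below the threshold are
#' discarded from both the test and the reference metric series — the
#' assumption being that both devices are affected by the same artifact.
#'
#' @param test_windows,ref_windows [windowed_metrics()] series on the same
#'   window grid.
#' @param ref_record the reference [ppg_record()] from which gating pSQI is
#'   computed (raw signal), or a precomputed `windowed_metrics` pSQI series
#'   on the same grid.
#' @param threshold pSQI threshold in percent (default 40).
#' @param p a [psqi_params()].
#' @return `list(test, ref, mask, psqi)`: the gated series, the logical
#'   keep-mask, and the reference pSQI values used.
#' @export
quality_gate <- function(test_windows, ref_windows, ref_record,
                         threshold = 40, p = psqi_params()) {
  stopifnot(inherits(test_windows, "windowed_metrics"),
            inherits(ref_windows, "windowed_metrics"))
  same_grid <- function(a, b) {
    isTRUE(all.equal(attr(a, "window_s"), attr(b, "window_s"))) &&
      isTRUE(all.equal(attr(a, "step_s"), attr(b, "step_s"))) &&
      nrow(a) == nrow(b) && isTRUE(all.equal(a$start, b$start))
  }
  if (!same_grid(test_windows, ref_windows)) {
    stop("test and reference series are on different window grids")
  }
  wp <- window_params(attr(test_windows, "window_s"),
                      attr(test_windows, "step_s"))
  qs <- if (inherits(ref_record, "windowed_metrics")) ref_record
        else psqi_windowed(ref_record, wp, p)
  if (!same_grid(qs, ref_windows)) {
    stop("reference pSQI series is on a different window grid")
  }
  mask <- !is.na(qs$value) & qs$value >= threshold
  sub <- function(wm) {
    windowed_metrics(wm$start[mask], wm$value[mask],
                     attr(wm, "window_s"), attr(wm, "step_s"),
                     metric = attr(wm, "metric"))
  }
  list(test = sub(test_windows), ref = sub(ref_windows),
       mask = mask, psqi = qs$value)
}

#' Per-window best-channel selection
#'
#' For multi-site acquisition (e.g. finger and ear PPG), picks per window
#' the channel with the highest mean quality; exact ties go to the first
#' channel in the supplied order.
#'
#' @param channels named list; each element is a list with fields `record`
#'   (a [ppg_record()]) and `quality` (a [quality_vector()] or a
#'   `windowed_metrics` pSQI series).
#' @param wp a [window_params()].
#' @return `data.frame(start, channel, score)` with one row per window.
#' @export
select_best_channel <- function(channels, wp) {
  if (!length(channels)) stop("need at least one channel")
  if (is.null(names(channels))) {
    names(channels) <- paste0("ch", seq_along(channels))
  }
  scores <- lapply(channels, function(ch) {
    q <- ch$quality
    if (inherits(q, "windowed_metrics")) {
      w <- window_iter(ch$record, wp)
      if (!isTRUE(all.equal(q$start[seq_len(nrow(w))], w$start))) {
        stop("pSQI series grid does not match the requested windows")
      }
      q$value
    } else if (inherits(q, "quality_vector")) {
      w <- window_iter(ch$record, wp)
      vapply(seq_len(nrow(w)), function(k) {
        i0 <- floor(w$start[k] / q$res) + 1L
        i1 <- min(length(q$scores), ceiling(w$end[k] / q$res))
        mean(q$scores[i0:i1], na.rm = TRUE)
      }, numeric(1))
    } else stop("each channel needs a quality_vector or pSQI series")
  })
  m <- do.call(cbind, scores)
  w <- window_iter(channels[[1]]$record, wp)
  pick <- apply(m, 1, which.max)  # which.max: first index wins ties
  data.frame(start = w$start, channel = names(channels)[pick],
             score = m[cbind(seq_len(nrow(m)), pick)])
}
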