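#' Beat morphology template
#'
#' A pulse wave is rendered as two Gaussian bumps per beat: a systolic peak
#' and a smaller dicrotic (reflected) wave. Widths and the dicrotic delay
#' are fractions of the inter-beat interval; the systolic peak sits at a
#' fixed latency of 0.2 s after beat onset (capped at 0.35 IBI for short
#' beats), so detected peak-to-peak intervals track the true onset-to-onset
#' intervals. The dicrotic latency is likewise capped at 0.25 s so that at
#' slow heart rates the dicrotic bump stays inside a detector's refractory
#' span, as it does physiologically.
#'
#' @param systolic_amp systolic amplitude (a.u., > 0).
#' @param systolic_width Gaussian SD of the systolic bump, fraction of IBI.
#' @param dicrotic_amp dicrotic amplitude (a.u., < systolic_amp).
#' @param dicrotic_delay delay of the dicrotic bump after the systolic peak,
#'   fraction of IBI, in (0, 1).
#' @param dicrotic_width Gaussian SD of the dicrotic bump, fraction of IBI.
#' @param dc_offset constant baseline (a.u.).
#' @return object of class `beat_template`.
#' @export
beat_template <- function(systolic_amp = 1.0, systolic_width = 0.07,
                          dicrotic_amp = 0.35, dicrotic_delay = 0.25,
                          dicrotic_width = 0.09, dc_offset = 0) {
  if (systolic_amp <= 0) stop("systolic_amp must be > 0")
  if (dicrotic_delay <= 0 || dicrotic_delay >= 1) {
    stop("dicrotic_delay must lie in (0, 1)")
  }
  if (dicrotic_amp >= systolic_amp) stop("dicrotic_amp must be < systolic_amp")
  structure(list(systolic_amp = systolic_amp, systolic_width = systolic_width,
                 dicrotic_amp = dicrotic_amp, dicrotic_delay = dicrotic_delay,
                 dicrotic_width = dicrotic_width, dc_offset = dc_offset),
            class = "beat_template")
}

#' Artifact specification
#'
#' Artifact events are placed by a Poisson process with exponentially
#' distributed event durations (mean `mean_event_s`), with the onset rate
#' chosen as `-log(1 - duty_cycle)/mean_event_s` so that the expected
#' fraction of the recording covered by at least one event equals
#' `duty_cycle`.
#'
#' @param kind one of `"motion_burst"`, `"baseline_wander"`, `"clipping"`,
#'   `"flatline"`.
#' @param duty_cycle target fraction of the recording affected, in `[0,1]`.
#' @param mean_event_s mean event duration in seconds (> 0).
#' @param amplitude artifact amplitude (a.u.); for `clipping` this is the
#'   saturation level, for `motion_burst`/`baseline_wander` the added noise
#'   amplitude.
#' @return object of class `artifact_spec`.
#' @export
artifact_spec <- function(kind = c("motion_burst", "baseline_wander",
                                   "clipping", "flatline"),
                          duty_cycle = 0.1, mean_event_s = 3,
                          amplitude = 2) {
  kind <- match.arg(kind)
  if (duty_cycle < 0 || duty_cycle > 1) stop("duty_cycle must lie in [0,1]")
  if (mean_event_s <= 0) stop("mean_event_s must be > 0")
  structure(list(kind = kind, duty_cycle = duty_cycle,
                 mean_event_s = mean_event_s, amplitude = amplitude),
            class = "artifact_spec")
}

#' Simulation specification
#'
#' Parameters of the synthetic beat-train generator: successive inter-beat
#' intervals are `60000/mean_hr` ms plus Gaussian jitter plus occasional
#' large excursions ("jumps") of `jump_magnitude` ms that alternate in sign
#' between successive jump events, clipped to the physiologically plausible
#' range 250-2000 ms.
#'
#' @param mean_hr mean heart rate in bpm, in `[30, 220]`.
#' @param jitter_sd SD of Gaussian successive-interval noise, ms (>= 0).
#' @param jump_prob per-beat probability of a large interval excursion.
#' @param jump_magnitude excursion magnitude in ms.
#' @param duration recording duration in seconds (> 0).
#' @param fs sampling rate in Hz (>= 25).
#' @param template a [beat_template()].
#' @param artifacts list of [artifact_spec()] objects.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(mean_hr = 70, jitter_sd = 30, jump_prob = 0,
                            jump_magnitude = 0, duration = 180, fs = 100,
                            template = beat_template(), artifacts = list(),
                            seed = 1L) {
  if (mean_hr < 30 || mean_hr > 220) stop("mean_hr must lie in [30, 220] bpm")
  if (fs < 25) stop("fs must be >= 25 Hz")
  if (duration <= 0) stop("duration must be > 0")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  if (jump_prob < 0 || jump_prob > 1) stop("jump_prob must lie in [0,1]")
  stopifnot(inherits(template, "beat_template"))
  if (!all(vapply(artifacts, inherits, TRUE, "artifact_spec"))) {
    stop("artifacts must be a list of artifact_spec objects")
  }
  structure(list(mean_hr = mean_hr, jitter_sd = jitter_sd,
                 jump_prob = jump_prob, jump_magnitude = jump_magnitude,
                 duration = duration, fs = fs, template = template,
                 artifacts = artifacts, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a ground-truth inter-beat-interval series
#'
#' Draws successive intervals from the generative model of
#' [simulation_spec()] until the cumulative beat time covers the requested
#' duration. Reproducible given the seed; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [simulation_spec()].
#' @return an [ibi_series()]; beat onsets start at t = 0 and the timestamp
#'   of interval k is the time of its second beat.
#' @export
generate_ibi_series <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  base <- 60000 / spec$mean_hr
  dur_ms <- spec$duration * 1000
  with_seed(spec$seed, {
    n_guess <- ceiling(dur_ms / base * 1.5) + 16L
    intervals <- numeric(0)
    jump_sign <- 1
    repeat {
      iv <- base + stats::rnorm(n_guess, 0, spec$jitter_sd)
      jumps <- stats::runif(n_guess) < spec$jump_prob
      if (any(jumps)) {
        idx <- which(jumps)
        signs <- jump_sign * (-1)^(seq_along(idx) - 1L)
        iv[idx] <- iv[idx] + signs * spec$jump_magnitude
        jump_sign <- -signs[length(signs)]
      }
      intervals <- c(intervals, pmin(2000, pmax(250, iv)))
      if (sum(intervals) >= dur_ms) break
    }
    keep <- which(cumsum(intervals) >= dur_ms)[1]
    intervals <- intervals[seq_len(keep)]
    ibi_series(intervals, cumsum(intervals) / 1000,
               duration = spec$duration)
  })
}

#' Render a PPG waveform from an interval series
#'
#' Each beat occupies its interval `[t_{k-1}, t_k)`; the systolic bump is
#' centred at `t_{k-1} + min(0.2 s, 0.35 IBI)` and the dicrotic bump
#' `dicrotic_delay * IBI` later. Record length is `round(sum(IBI) * fs)`
#' samples.
#'
#' @param ibi an [ibi_series()].
#' @param fs target sampling rate in Hz (>= 25).
#' @param template a [beat_template()].
#' @param channel channel name for the returned record.
#' @return a [ppg_record()] with attribute `peak_times` giving the true
#'   systolic peak times (s) of each beat.
#' @export
render_ppg <- function(ibi, fs, template = beat_template(),
                       channel = "ppg_sim") {
  stopifnot(inherits(ibi, "ibi_series"))
  if (length(ibi) == 0L) stop("`ibi` must contain at least one interval")
  if (fs < 25) stop("fs must be >= 25 Hz")
  iv_s <- ibi$intervals / 1000
  onsets <- c(0, cumsum(iv_s)[-length(iv_s)])
  total <- sum(iv_s)
  n <- round(total * fs)
  t <- (seq_len(n) - 1) / fs
  x <- rep(template$dc_offset, n)
  sys_c <- onsets + pmin(0.2, 0.35 * iv_s)
  dic_c <- sys_c + pmin(0.25, template$dicrotic_delay * iv_s)
  sys_sd <- template$systolic_width * iv_s
  dic_sd <- template$dicrotic_width * iv_s
  for (k in seq_along(iv_s)) {
    lo <- max(1L, floor((sys_c[k] - 4 * sys_sd[k]) * fs) + 1L)
    hi <- min(n, ceiling((dic_c[k] + 4 * dic_sd[k]) * fs) + 1L)
    if (lo > hi) next
    tk <- t[lo:hi]
    bump <- template$systolic_amp *
      exp(-0.5 * ((tk - sys_c[k]) / sys_sd[k])^2)
    if (template$dicrotic_amp > 0) {
      bump <- bump + template$dicrotic_amp *
        exp(-0.5 * ((tk - dic_c[k]) / dic_sd[k])^2)
    }
    x[lo:hi] <- x[lo:hi] + bump
  }
  rec <- ppg_record(x, fs, channel = channel)
  attr(rec, "peak_times") <- sys_c
  rec
}

# internal: seeded Poisson/exponential event placement hitting an expected
# covered fraction equal to duty_cycle
place_events <- function(duration, duty_cycle, mean_event_s) {
  if (duty_cycle <= 0) return(matrix(numeric(0), ncol = 2))
  if (duty_cycle >= 1) return(matrix(c(0, duration), ncol = 2))
  rate <- -log(1 - duty_cycle) / mean_event_s
  n <- stats::rpois(1, rate * duration)
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  onset <- sort(stats::runif(n, 0, duration))
  len <- stats::rexp(n, 1 / mean_event_s)
  cbind(onset, pmin(duration, onset + len))
}

# internal: merge overlapping [on, off) event intervals
merge_events <- function(ev) {
  if (nrow(ev) <= 1) return(ev)
  ev <- ev[order(ev[, 1]), , drop = FALSE]
  out <- ev[1, , drop = FALSE]
  for (i in 2:nrow(ev)) {
    if (ev[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], ev[i, 2])
    } else out <- rbind(out, ev[i, ])
  }
  out
}

#' Inject artifacts and derive ground-truth quality labels
#'
#' Returns a corrupted copy of the record plus binary quality labels on a
#' `label_res` grid. A segment is labelled bad iff an artifact event
#' overlaps more than half of it; flatline and clipping events mark a
#' segment bad on any overlap, since even brief saturation destroys the
#' waveform. A trailing partial segment (when the duration is not a
#' multiple of `label_res`) is dropped.
#'
#' @param rec a [ppg_record()].
#' @param specs list of [artifact_spec()] objects.
#' @param label_res label resolution in seconds (default 0.5).
#' @param seed integer seed controlling event placement and noise.
#' @return `list(record = corrupted ppg_record, quality = quality_vector,
#'   events = data.frame(kind, onset, offset))`.
#' @export
inject_artifacts <- function(rec, specs, label_res = 0.5, seed = 1L) {
  stopifnot(inherits(rec, "ppg_record"))
  if (!all(vapply(specs, inherits, TRUE, "artifact_spec"))) {
    stop("specs must be a list of artifact_spec objects")
  }
  fs <- rec$fs
  n <- length(rec$signal)
  duration <- n / fs
  n_seg <- floor(duration / label_res)
  x <- rec$signal
  ev_all <- data.frame(kind = character(0), onset = numeric(0),
                       offset = numeric(0))
  hard <- rep(FALSE, n_seg)  # any-overlap rule (flatline, clipping)
  soft_overlap <- rep(0, n_seg)  # accumulated overlap seconds per segment

  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    ev <- with_seed(derive_seed(seed, si), {
      e <- place_events(duration, sp$duty_cycle, sp$mean_event_s)
      if (nrow(e)) e <- merge_events(e)
      e
    })
    if (!nrow(ev)) next
    ev_all <- rbind(ev_all, data.frame(kind = sp$kind, onset = ev[, 1],
                                       offset = ev[, 2]))
    for (j in seq_len(nrow(ev))) {
      i0 <- floor(ev[j, 1] * fs) + 1L
      i1 <- min(n, ceiling(ev[j, 2] * fs))
      if (i0 > i1) next
      idx <- i0:i1
      x[idx] <- with_seed(derive_seed(seed, si, j), {
        corrupt_samples(x[idx], sp, fs)
      })
      # label bookkeeping
      s0 <- floor(ev[j, 1] / label_res)
      s1 <- min(n_seg - 1L, floor((ev[j, 2] - 1e-12) / label_res))
      if (s1 < s0) next
      segs <- s0:s1
      ov <- pmin(ev[j, 2], (segs + 1) * label_res) -
        pmax(ev[j, 1], segs * label_res)
      if (sp$kind %in% c("flatline", "clipping")) {
        hard[segs + 1L] <- hard[segs + 1L] | (ov > 0)
      } else {
        soft_overlap[segs + 1L] <- soft_overlap[segs + 1L] + ov
      }
    }
  }
  bad <- hard | (soft_overlap > label_res / 2)
  out <- ppg_record(x, fs, channel = rec$channel)
  q <- quality_vector(as.numeric(!bad), res = label_res)
  out$quality <- q
  list(record = out, quality = q, events = ev_all)
}

# internal: corrupt one event's samples in place (RNG already seeded)
corrupt_samples <- function(seg, sp, fs) {
  m <- length(seg)
  switch(sp$kind,
    motion_burst = {
      # low-pass-correlated broadband noise burst
      e <- stats::rnorm(m)
      e <- as.numeric(stats::filter(e, 0.7, method = "recursive"))
      sc <- stats::sd(e)
      if (!is.finite(sc) || sc < 1e-12) sc <- 1
      seg + sp$amplitude * e / sc
    },
    baseline_wander = {
      f <- stats::runif(1, 0.15, 0.4)
      ph <- stats::runif(1, 0, 2 * pi)
      seg + sp$amplitude * sin(2 * pi * f * (seq_len(m) - 1) / fs + ph)
    },
    clipping = pmin(seg, sp$amplitude),
    flatline = rep(seg[1], m)
  )
}
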