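#' Study protocol for a simulated validation session
#'
#' Orders a set of named experimental conditions, each with its own
#' generator settings, emulating a within-subject protocol of timed
#' conditions separated by rest periods.
#'
#' @param conditions named list of [simulation_spec()] objects (names must
#'   be unique). The `duration` field of each spec is overridden by
#'   `condition_duration`.
#' @param condition_duration length of each condition in seconds (default
#'   180, i.e. 3 minutes).
#' @param rest_duration rest between conditions in seconds (default 60).
#' @param n_subjects number of simulated subjects (>= 1).
#' @param seed study-level seed.
#' @return object of class `study_protocol`.
#' @export
study_protocol <- function(conditions = default_conditions(),
                           condition_duration = 180, rest_duration = 60,
                           n_subjects = 15, seed = 1L) {
  if (is.null(names(conditions)) || anyDuplicated(names(conditions))) {
    stop("conditions must be a uniquely named list")
  }
  if (!all(vapply(conditions, inherits, TRUE, "simulation_spec"))) {
    stop("each condition must be a simulation_spec")
  }
  if (condition_duration <= 0 || rest_duration < 0) {
    stop("durations must be positive")
  }
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  structure(list(conditions = conditions,
                 condition_duration = condition_duration,
                 rest_duration = rest_duration,
                 n_subjects = as.integer(n_subjects),
                 seed = as.integer(seed)),
            class = "study_protocol")
}

#' Default four-condition protocol
#'
#' Baseline (slow-paced breathing: low HR, high beat-to-beat variability),
#' an easy and a difficult mental-arithmetic task (rising HR, falling
#' variability) and a movement condition. Artifact severity increases
#' monotonically from baseline to movement, emulating a wearable channel
#' that degrades under motion.
#'
#' @param fs sampling rate for all conditions (Hz).
#' @return named list of [simulation_spec()] objects.
#' @export
default_conditions <- function(fs = 100) {
  list(
    baseline = simulation_spec(
      mean_hr = 64, jitter_sd = 45, jump_prob = 0.12, jump_magnitude = 70,
      fs = fs,
      artifacts = list(artifact_spec("motion_burst", duty_cycle = 0.02,
                                     mean_event_s = 2, amplitude = 2.5))),
    math_easy = simulation_spec(
      mean_hr = 72, jitter_sd = 35, jump_prob = 0.08, jump_magnitude = 65,
      fs = fs,
      artifacts = list(artifact_spec("motion_burst", duty_cycle = 0.06,
                                     mean_event_s = 2.5, amplitude = 2.5))),
    math_difficult = simulation_spec(
      mean_hr = 79, jitter_sd = 26, jump_prob = 0.05, jump_magnitude = 60,
      fs = fs,
      artifacts = list(artifact_spec("motion_burst", duty_cycle = 0.12,
                                     mean_event_s = 3, amplitude = 3),
                       artifact_spec("baseline_wander", duty_cycle = 0.08,
                                     mean_event_s = 4, amplitude = 1.5))),
    movement = simulation_spec(
      mean_hr = 76, jitter_sd = 30, jump_prob = 0.07, jump_magnitude = 60,
      fs = fs,
      artifacts = list(artifact_spec("motion_burst", duty_cycle = 0.22,
                                     mean_event_s = 3, amplitude = 3.5),
                       artifact_spec("clipping", duty_cycle = 0.05,
                                     mean_event_s = 2, amplitude = 0.55),
                       artifact_spec("baseline_wander", duty_cycle = 0.12,
                                     mean_event_s = 4, amplitude = 2)))
  )
}

#' Simulate a paired-device validation study
#'
#' For every subject and condition, one ground-truth interval series is
#' drawn (with subject-level variation of mean HR and variability) and
#' rendered twice: a clean "reference" record (research-grade device) and a
#' "device" record to which the condition's artifacts plus mild sensor
#' noise are applied. Ground-truth IBIs and 0.5 s quality labels are kept
#' alongside. Deterministic per (subject, condition, seed).
#'
#' @param protocol a [study_protocol()].
#' @return object of class `ppg_study`: a list of sessions, each
#'   `list(subject, condition, reference, device, ibi, quality, events)`.
#' @export
simulate_study <- function(protocol = study_protocol()) {
  stopifnot(inherits(protocol, "study_protocol"))
  sessions <- list()
  cn <- names(protocol$conditions)
  for (s in seq_len(protocol$n_subjects)) {
    # stable per-subject physiology offsets
    subj <- with_seed(derive_seed(protocol$seed, s), {
      list(hr_off = stats::rnorm(1, 0, 6),
           jit_mul = exp(stats::rnorm(1, 0, 0.3)))
    })
    for (ci in seq_along(cn)) {
      base <- protocol$conditions[[ci]]
      sp <- simulation_spec(
        mean_hr = min(220, max(30, base$mean_hr + subj$hr_off)),
        jitter_sd = base$jitter_sd * subj$jit_mul,
        jump_prob = base$jump_prob, jump_magnitude = base$jump_magnitude,
        duration = protocol$condition_duration, fs = base$fs,
        template = base$template, artifacts = base$artifacts,
        seed = derive_seed(protocol$seed, s, ci))
      ibi <- generate_ibi_series(sp)
      crop <- function(rec) {
        n <- round(protocol$condition_duration * rec$fs)
        out <- ppg_record(rec$signal[seq_len(min(n, length(rec$signal)))],
                          rec$fs, channel = rec$channel)
        attr(out, "peak_times") <- attr(rec, "peak_times")
        out
      }
      ref <- crop(render_ppg(ibi, sp$fs, sp$template, channel = "reference"))
      dev_clean <- crop(render_ppg(ibi, sp$fs, sp$template,
                                   channel = "device"))
      inj <- inject_artifacts(dev_clean, sp$artifacts,
                              seed = derive_seed(protocol$seed, s, ci, 99))
      dev <- inj$record
      # mild always-on sensor noise on the wearable channel
      dev$signal <- dev$signal + with_seed(derive_seed(protocol$seed, s, ci, 7),
        stats::rnorm(length(dev$signal), 0, 0.02))
      sessions[[length(sessions) + 1L]] <- list(
        subject = s, condition = cn[ci], reference = ref, device = dev,
        ibi = ibi, quality = inj$quality, events = inj$events,
        spec = sp)
    }
  }
  structure(list(sessions = sessions, protocol = protocol),
            class = "ppg_study")
}

#' @export
print.ppg_study <- function(x, ...) {
  cat(sprintf("<ppg_study> %d subjects x %d conditions = %d paired sessions (%g s each)\n",
              x$protocol$n_subjects, length(x$protocol$conditions),
              length(x$sessions), x$protocol$condition_duration))
  invisible(x)
}

#' Write a simulated study to disk as session CSVs plus a JSON manifest
#'
#' Each session becomes two session CSV files (reference and device
#' channels, 12-bit ADC quantised) with sidecar metadata, plus plain-text
#' ground truth (IBI series and quality labels). `manifest.json` indexes
#' subject, condition, seed and file paths.
#'
#' @param study a `ppg_study`.
#' @param dir output directory (created if missing).
#' @return the manifest as a data.frame, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "ppg_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (sess in study$sessions) {
    stem <- sprintf("sub%02d_%s", sess$subject, sess$condition)
    dev_path <- file.path(dir, paste0(stem, "_device.csv"))
    ref_path <- file.path(dir, paste0(stem, "_reference.csv"))
    meta <- list(participant = sprintf("sub%02d", sess$subject),
                 condition = sess$condition, fs = sess$device$fs,
                 start_time = "1970-01-01T00:00:00Z")
    write_session(list(device = adc_quantize(sess$device$signal)),
                  dev_path, fs = sess$device$fs, meta = meta,
                  quality = list(device = sess$quality))
    write_session(list(reference = adc_quantize(sess$reference$signal)),
                  ref_path, fs = sess$reference$fs, meta = meta)
    truth_path <- file.path(dir, paste0(stem, "_truth.json"))
    jsonlite::write_json(list(intervals_ms = sess$ibi$intervals,
                              times_s = sess$ibi$times,
                              quality = sess$quality$scores),
                         truth_path, digits = NA)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sess$subject, condition = sess$condition,
      device = basename(dev_path), reference = basename(ref_path),
      truth = basename(truth_path), seed = sess$spec$seed)
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(manifest)
}
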