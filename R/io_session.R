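#' Quantise a float signal to ADC counts
#'
#' Maps the signal range linearly onto unsigned integer counts, emulating
#' the raw output of a 10/12-bit acquisition front end.
#'
#' @param x numeric signal.
#' @param bits ADC resolution in bits (default 12).
#' @param range optional `c(lo, hi)` mapped to `0 .. 2^bits - 1`; defaults
#'   to the signal range.
#' @return integer vector of counts.
#' @export
adc_quantize <- function(x, bits = 12, range = NULL) {
  if (is.null(range)) range <- range(x)
  if (diff(range) <= 0) return(rep(0L, length(x)))
  full <- 2^bits - 1
  as.integer(round(pmin(full, pmax(0, (x - range[1]) / diff(range) * full))))
}

#' Write a session CSV with sidecar metadata
#'
#' One row per sample: one column per channel (integer ADC counts), an
#' `event_code` column (0 = no event) and, per annotated channel, a
#' `<channel>_quality` column with each 0.5 s label repeated per sample.
#' Comma separator, header row, LF line endings. Metadata (participant,
#' condition, sampling rate, UTC start time, ADC bits) goes to a JSON
#' sidecar at `<path>.meta.json`.
#'
#' @param channels named list of equal-length integer vectors.
#' @param path CSV output path.
#' @param fs sampling rate in Hz.
#' @param events optional: either a per-sample integer vector of event
#'   codes, or a `data.frame(onset, offset, code)` in seconds, expanded to
#'   codes on `[onset, offset)` rows.
#' @param quality optional named list of [quality_vector()]s keyed by
#'   channel name.
#' @param meta named list of additional metadata fields.
#' @param adc_bits ADC resolution recorded in the sidecar.
#' @return `path`, invisibly.
#' @export
write_session <- function(channels, path, fs, events = NULL, quality = NULL,
                          meta = list(), adc_bits = 12) {
  if (is.null(names(channels)) || any(names(channels) == "")) {
    stop("`channels` must be a fully named list")
  }
  n <- unique(vapply(channels, length, integer(1)))
  if (length(n) != 1) stop("all channels must have equal length")
  df <- as.data.frame(lapply(channels, as.integer))
  ev <- if (is.null(events)) rep(0L, n)
        else if (is.data.frame(events)) events_to_codes(events, n, fs)
        else as.integer(events)
  if (length(ev) != n) stop("event vector length must match channels")
  df$event_code <- ev
  if (!is.null(quality)) {
    for (ch in names(quality)) {
      q <- quality[[ch]]
      stopifnot(inherits(q, "quality_vector"))
      per_sample <- rep(q$scores, each = round(q$res * fs))
      per_sample <- c(per_sample, rep(NA_real_,
                                      max(0, n - length(per_sample))))
      df[[paste0(ch, "_quality")]] <- per_sample[seq_len(n)]
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  side <- utils::modifyList(
    list(fs = fs, n_samples = n, channels = names(channels),
         adc_bits = adc_bits, format_version = 1L,
         start_time = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")),
    meta)
  jsonlite::write_json(side, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Expand event spans to a per-sample code vector
#'
#' @param events `data.frame(onset, offset, code)` in seconds.
#' @param n number of samples.
#' @param fs sampling rate.
#' @return integer vector of length `n`; code applies on `[onset, offset)`.
#' @export
events_to_codes <- function(events, n, fs) {
  ev <- rep(0L, n)
  for (j in seq_len(nrow(events))) {
    i0 <- floor(events$onset[j] * fs) + 1L
    i1 <- min(n, ceiling(events$offset[j] * fs))
    if (i0 <= i1 && i0 <= n) ev[i0:i1] <- as.integer(events$code[j])
  }
  ev
}

#' Read a session CSV written by [write_session()]
#'
#' Validates the row structure (a ragged/truncated row is reported with
#' its row number), splits channel, event and quality columns, and
#' restores quality vectors from their per-sample repetition.
#'
#' @param path CSV path; the `<path>.meta.json` sidecar is read if present.
#' @return `list(channels, event_code, quality, meta)` of class
#'   `session_record`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such session file: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "")
  if (length(nf) < 2) stop("session file has no data rows: ", path)
  bad <- which(nf != nf[1])
  if (length(bad)) {
    stop(sprintf("malformed session file %s: row %d has %d fields, expected %d",
                 path, bad[1], nf[bad[1]], nf[1]))
  }
  df <- utils::read.csv(path, check.names = FALSE)
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else list(fs = NA_real_)
  if (!is.null(meta$format_version) && meta$format_version != 1L) {
    stop("unknown session format version: ", meta$format_version)
  }
  if (!"event_code" %in% names(df)) {
    stop("session file missing event_code column: ", path)
  }
  qcols <- grep("_quality$", names(df), value = TRUE)
  chans <- setdiff(names(df), c("event_code", qcols))
  quality <- list()
  fs <- meta$fs
  for (qc in qcols) {
    per <- round(0.5 * fs)
    v <- df[[qc]]
    n_seg <- floor(length(v) / per)
    scores <- v[seq(1L, by = per, length.out = n_seg)]
    quality[[sub("_quality$", "", qc)]] <- quality_vector(scores, res = 0.5)
  }
  structure(list(channels = as.list(df[chans]),
                 event_code = as.integer(df$event_code),
                 quality = quality, meta = meta),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record> %d samples, channels: %s, fs=%s Hz\n",
              length(x$event_code), paste(names(x$channels), collapse = ", "),
              format(x$meta$fs)))
  invisible(x)
}
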