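#' Parse and validate an experiment configuration file
#'
#' JSON file describing the study protocol: condition names, timed
#' acquisition with a maximum duration, channels (at most four may be
#' marked for real-time plotting), the data root directory and an optional
#' biofeedback block (metric name, window length, step interval, metric
#' range). Defaults are filled in; all violations are reported together.
#'
#' @param path path to a JSON file, or an already-parsed list.
#' @return validated config list of class `experiment_config`.
#' @export
parse_experiment_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else path
  defaults <- list(conditions = "session", timed_acquisition = TRUE,
                   max_time_seconds = 180, data_root = ".",
                   biofeedback = NULL)
  channels <- cfg$channels   # kept aside: unnamed lists and modifyList
  cfg$channels <- NULL       # do not mix
  cfg <- utils::modifyList(defaults, cfg, keep.null = TRUE)
  cfg$channels <- if (is.null(channels)) list() else channels
  problems <- character(0)
  if (!length(cfg$conditions)) {
    problems <- c(problems, "at least one condition name is required")
  }
  if (anyDuplicated(cfg$conditions)) {
    problems <- c(problems, "condition names must be unique")
  }
  if (isTRUE(cfg$timed_acquisition) &&
      (!is.numeric(cfg$max_time_seconds) || cfg$max_time_seconds <= 0)) {
    problems <- c(problems,
                  "timed_acquisition requires max_time_seconds > 0")
  }
  ch <- cfg$channels
  if (length(ch)) {
    if (is.data.frame(ch)) ch <- split(ch, seq_len(nrow(ch)))
    plotted <- sum(vapply(ch, function(c) isTRUE(c$plot) ||
                            isTRUE(as.logical(c$plot)), logical(1)))
    if (plotted > 4) {
      problems <- c(problems, sprintf(
        "%d channels marked for plotting; a maximum of four is allowed",
        plotted))
    }
  }
  if (!is.null(cfg$biofeedback)) {
    bf <- cfg$biofeedback
    need <- c("metric", "window_s", "step_s", "min", "max")
    miss <- setdiff(need, names(bf))
    if (length(miss)) {
      problems <- c(problems, paste("biofeedback block missing fields:",
                                    paste(miss, collapse = ", ")))
    } else if (bf$min >= bf$max) {
      problems <- c(problems, "biofeedback min must be < max")
    }
  }
  if (length(problems)) {
    stop("invalid experiment config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = c("experiment_config", "list"))
}

#' Parse and validate a software configuration file
#'
#' Acquisition parameters: sampling rate (10-10,000 samples per second),
#' serial baudrate, and the synchronization role — one computer acts as a
#' TCP `server`, the others as `client`s that must name the server
#' address.
#'
#' @param path path to a JSON file, or an already-parsed list.
#' @return validated config list of class `software_config`.
#' @export
parse_software_config <- function(path) {
  cfg <- if (is.character(path)) jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else path
  defaults <- list(sampling_rate = 250, baudrate = 115200,
                   role = "standalone", server_address = NULL,
                   port = 5005)
  cfg <- utils::modifyList(defaults, cfg, keep.null = TRUE)
  problems <- character(0)
  if (!is.numeric(cfg$sampling_rate) || cfg$sampling_rate < 10 ||
      cfg$sampling_rate > 10000) {
    problems <- c(problems,
                  "sampling_rate must lie in 10..10000 samples per second")
  }
  if (!cfg$role %in% c("server", "client", "standalone")) {
    problems <- c(problems, "role must be server, client or standalone")
  }
  if (identical(cfg$role, "client") &&
      (is.null(cfg$server_address) || !nzchar(cfg$server_address))) {
    problems <- c(problems, "client role requires server_address")
  }
  if (!is.numeric(cfg$port) || cfg$port < 1 || cfg$port > 65535) {
    problems <- c(problems, "port must lie in 1..65535")
  }
  if (length(problems)) {
    stop("invalid software config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  structure(cfg, class = c("software_config", "list"))
}
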