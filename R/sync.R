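# Multi-node start-trigger synchronization: a line-delimited text protocol
# (HELLO/ACK/START/STOP/MARK/ERROR as one JSON object per line) with
# transport-agnostic server and client state machines. The state machines
# are driven either over an in-process loopback (fully testable) or over
# TCP socket connections via the thin wrappers at the bottom.

SYNC_TYPES <- c("HELLO", "ACK", "START", "STOP", "MARK", "ERROR")

#' Serialize / parse a synchronization protocol message
#'
#' Messages are single lines: the message type followed by a space and a
#' minified JSON object of fields, e.g.
#' `START {"session_id":"s1","utc_time":"2024-01-01T00:00:00Z"}`.
#' `sync_parse` rejects unknown types and malformed JSON without side
#' effects.
#'
#' @param msg a list with a `type` field (one of HELLO, ACK, START, STOP,
#'   MARK, ERROR) plus type-specific fields.
#' @return `sync_serialize`: a single-line character string.
#' @export
sync_serialize <- function(msg) {
  if (is.null(msg$type) || !msg$type %in% SYNC_TYPES) {
    stop("unknown message type: ", format(msg$type))
  }
  fields <- msg[setdiff(names(msg), "type")]
  body <- if (length(fields)) {
    as.character(jsonlite::toJSON(fields, auto_unbox = TRUE))
  } else "{}"
  paste(msg$type, body)
}

#' @rdname sync_serialize
#' @param line a single protocol line.
#' @return `sync_parse`: the message as a list with a `type` field.
#' @export
sync_parse <- function(line) {
  line <- sub("\r$", "", line)
  sp <- regexpr(" ", line)
  type <- if (sp > 0) substr(line, 1, sp - 1) else line
  if (!type %in% SYNC_TYPES) stop("unknown message type: ", type)
  body <- if (sp > 0) substr(line, sp + 1, nchar(line)) else "{}"
  fields <- tryCatch(jsonlite::fromJSON(body, simplifyVector = TRUE),
                     error = function(e) stop("malformed message body: ",
                                              conditionMessage(e)))
  c(list(type = type), as.list(fields))
}

#' Server-side synchronization state machine
#'
#' Registers clients on HELLO (replying ACK), broadcasts START/STOP for a
#' session, and relays MARK events. Transport-agnostic: feed it lines with
#' `$handle(line)` and deliver its return value(s) back to the sender;
#' broadcast lines from `$start_session()` / `$stop_session()` go to every
#' registered client.
#'
#' @param config a [parse_software_config()] result (role must not be
#'   "client").
#' @return an environment with functions `handle`, `start_session`,
#'   `stop_session`, `clients`.
#' @export
sync_server_node <- function(config = parse_software_config(list(role = "server"))) {
  if (identical(config$role, "client")) stop("server node cannot have client role")
  clients <- character(0)
  session <- NULL
  handle <- function(line) {
    msg <- tryCatch(sync_parse(line), error = function(e) e)
    if (inherits(msg, "error")) {
      return(sync_serialize(list(type = "ERROR",
                                 reason = conditionMessage(msg))))
    }
    switch(msg$type,
      HELLO = {
        if (is.null(msg$client_id)) {
          return(sync_serialize(list(type = "ERROR",
                                     reason = "HELLO without client_id")))
        }
        if (!msg$client_id %in% clients) {
          clients <<- c(clients, msg$client_id)
        }
        sync_serialize(list(type = "ACK", client_id = msg$client_id))
      },
      MARK = sync_serialize(msg),  # relay
      sync_serialize(list(type = "ERROR",
                          reason = paste("unexpected", msg$type)))
    )
  }
  start_session <- function(session_id,
                            utc_time = format(Sys.time(),
                                              "%Y-%m-%dT%H:%M:%SZ",
                                              tz = "UTC")) {
    session <<- list(session_id = session_id, utc_time = utc_time)
    sync_serialize(list(type = "START", session_id = session_id,
                        utc_time = utc_time))
  }
  stop_session <- function() {
    if (is.null(session)) stop("no session in progress")
    line <- sync_serialize(list(type = "STOP",
                                session_id = session$session_id))
    session <<- NULL
    line
  }
  environment()
}

#' Client-side synchronization state machine
#'
#' Idle until HELLO/ACK completes; records only between START and STOP.
#' On STOP, session metadata (session id, server start timestamp, marks)
#' is written as `<out_dir>/<client_id>_<session_id>.json`. A STOP or MARK
#' before START is a protocol error and writes nothing; a duplicate START
#' for the same session id is ignored (idempotent).
#'
#' @param client_id unique client identifier.
#' @param out_dir directory for session metadata files.
#' @return an environment with `hello()` (returns the HELLO line),
#'   `handle(line)` (feed server lines; returns a reply line or `NULL`),
#'   `state()` and `session_file()`.
#' @export
sync_client_node <- function(client_id, out_dir = tempdir()) {
  state <- "idle"           # idle -> ready -> recording -> ready
  session <- NULL
  marks <- list()
  file_written <- NULL
  hello <- function() sync_serialize(list(type = "HELLO",
                                          client_id = client_id))
  handle <- function(line) {
    msg <- tryCatch(sync_parse(line), error = function(e) e)
    if (inherits(msg, "error")) {
      return(sync_serialize(list(type = "ERROR",
                                 reason = conditionMessage(msg))))
    }
    switch(msg$type,
      ACK = {
        if (state == "idle" && identical(msg$client_id, client_id)) {
          state <<- "ready"
        }
        NULL
      },
      START = {
        if (state == "idle") {
          return(sync_serialize(list(type = "ERROR",
                                     reason = "START before HELLO/ACK")))
        }
        if (state == "recording" &&
            identical(session$session_id, msg$session_id)) {
          return(NULL)  # duplicate START for same session: idempotent
        }
        session <<- list(session_id = msg$session_id,
                         utc_time = msg$utc_time)
        marks <<- list()
        state <<- "recording"
        NULL
      },
      MARK = {
        if (state != "recording") {
          return(sync_serialize(list(type = "ERROR",
                                     reason = "MARK outside session")))
        }
        marks[[length(marks) + 1L]] <<- msg[c("code", "state")]
        NULL
      },
      STOP = {
        if (state != "recording" ||
            !identical(session$session_id, msg$session_id)) {
          return(sync_serialize(list(type = "ERROR",
                                     reason = "STOP without matching START")))
        }
        path <- file.path(out_dir, sprintf("%s_%s.json", client_id,
                                           session$session_id))
        jsonlite::write_json(list(client_id = client_id,
                                  session_id = session$session_id,
                                  start_time = session$utc_time,
                                  marks = marks),
                             path, auto_unbox = TRUE)
        file_written <<- path
        session <<- NULL
        state <<- "ready"
        NULL
      },
      sync_serialize(list(type = "ERROR",
                          reason = paste("unexpected", msg$type)))
    )
  }
  environment()
}

#' Loopback synchronization run with simulated clients
#'
#' Drives the server and client state machines through a full session
#' lifecycle entirely in-process: HELLO/ACK registration, broadcast START,
#' optional MARK relay, broadcast STOP. Each client writes its session
#' metadata file; all files share the server's session id and start
#' timestamp.
#'
#' @param client_ids character vector of client identifiers.
#' @param session_id session identifier broadcast by the server.
#' @param out_dir directory for the clients' session files.
#' @param marks optional `data.frame(code, state)` of events to relay
#'   mid-session.
#' @return `data.frame(client_id, file, session_id, start_time)`.
#' @export
run_sync_loopback <- function(client_ids, session_id = "session1",
                              out_dir = tempdir(), marks = NULL) {
  server <- sync_server_node()
  nodes <- lapply(client_ids, sync_client_node, out_dir = out_dir)
  names(nodes) <- client_ids
  for (cl in nodes) {
    reply <- server$handle(cl$hello())
    cl$handle(reply)
  }
  start_line <- server$start_session(session_id)
  for (cl in nodes) cl$handle(start_line)
  if (!is.null(marks)) {
    for (j in seq_len(nrow(marks))) {
      line <- sync_serialize(list(type = "MARK", code = marks$code[j],
                                  state = marks$state[j]))
      relayed <- server$handle(line)
      for (cl in nodes) cl$handle(relayed)
    }
  }
  stop_line <- server$stop_session()
  for (cl in nodes) cl$handle(stop_line)
  do.call(rbind, lapply(client_ids, function(id) {
    path <- nodes[[id]]$file_written
    meta <- jsonlite::read_json(path, simplifyVector = TRUE)
    data.frame(client_id = id, file = path,
               session_id = meta$session_id,
               start_time = meta$start_time)
  }))
}

#' Run a synchronization server / client over TCP
#'
#' Thin socket transports for the state machines above, for real
#' multi-machine use: the server accepts `n_clients` connections, performs
#' registration, broadcasts START, waits `session_s`, broadcasts STOP.
#' The client connects, registers and follows the server's lifecycle.
#' Blocking, single-session helpers.
#'
#' @param config a [parse_software_config()] result.
#' @param n_clients number of clients the server waits for.
#' @param session_id,session_s session identifier and duration.
#' @param out_dir client-side output directory.
#' @param timeout socket timeout in seconds.
#' @return server: the broadcast session id, invisibly; client: the path
#'   of the written session file.
#' @export
run_sync_server <- function(config, n_clients = 1, session_id = "session1",
                            session_s = 1, timeout = 30) {
  server <- sync_server_node(config)
  cons <- vector("list", n_clients)
  on.exit(for (co in cons) if (!is.null(co)) try(close(co), silent = TRUE))
  for (i in seq_len(n_clients)) {
    co <- socketConnection(host = "0.0.0.0", port = config$port,
                           server = TRUE, blocking = TRUE, open = "r+",
                           timeout = timeout)
    writeLines(server$handle(readLines(co, n = 1)), co)
    cons[[i]] <- co
  }
  start_line <- server$start_session(session_id)
  for (co in cons) writeLines(start_line, co)
  Sys.sleep(session_s)
  stop_line <- server$stop_session()
  for (co in cons) writeLines(stop_line, co)
  invisible(session_id)
}

#' @rdname run_sync_server
#' @param client_id this client's identifier.
#' @export
run_sync_client <- function(config, client_id, out_dir = tempdir(),
                            timeout = 30) {
  if (!identical(config$role, "client")) stop("config role must be client")
  node <- sync_client_node(client_id, out_dir)
  co <- socketConnection(host = config$server_address, port = config$port,
                         blocking = TRUE, open = "r+", timeout = timeout)
  on.exit(try(close(co), silent = TRUE))
  writeLines(node$hello(), co)
  repeat {
    line <- readLines(co, n = 1)
    if (!length(line)) break
    reply <- node$handle(line)
    if (!is.null(reply)) writeLines(reply, co)
    if (!is.null(node$file_written)) break
  }
  node$file_written
}
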