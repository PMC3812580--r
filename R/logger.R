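# Session logging: CSV event logs whose header blocks record every active
# parameter, rewritten whenever the configuration changes, so a log file is
# self-describing and the exact detector settings behind every event can be
# recovered later.

#' Open (or reopen) a session log
#'
#' Creates the file if needed and appends a header block: '#'-prefixed
#' comment lines carrying the session start time, the buffering mode and
#' every parameter passed in `params`, followed by the CSV column line.
#' Reopening an existing path (e.g. after changing a threshold) appends a
#' fresh header block, so the file accumulates a full parameter history
#' while remaining one parseable CSV.
#'
#' Two buffering modes are offered. `"immediate"` writes each event row as
#' it is logged (10 ms-precision wireless style — rows survive a crash);
#' `"buffered"` accumulates rows in memory and flushes at
#' [close_session()] (wired style).
#'
#' @param path Log file path.
#' @param params Named list of parameters to record (threshold values,
#'   mapping id, ...).
#' @param mode `"immediate"` or `"buffered"`.
#' @return An environment of class `session_log`.
#' @examples
#' log <- open_session(tempfile(fileext = ".csv"),
#'                     params = unclass(strain_config()))
#' close_session(log)
#' @export
open_session <- function(path, params = list(),
                         mode = c("immediate", "buffered")) {
  mode <- match.arg(mode)
  header <- c(
    paste0("# session_start=", format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")),
    paste0("# mode=", mode),
    vapply(names(params), function(nm) paste0("# ", nm, "=", params[[nm]]),
           character(1)),
    "t_ms,iso_time,kind,magnitude,sound_id,gain"
  )
  ok <- tryCatch({
    con <- file(path, open = "a")
    writeLines(header, con)
    close(con)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(paste0("cannot open session log at '", path, "'"))
  log <- new.env(parent = emptyenv())
  log$path <- path
  log$mode <- mode
  log$open <- TRUE
  log$buffer <- list()
  class(log) <- "session_log"
  log
}

record_to_line <- function(rec) {
  iso <- if (!is.null(rec$iso_time)) rec$iso_time
         else format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")
  sprintf("%d,%s,%s,%s,%s,%s", as.integer(rec$t_ms), iso,
          rec$kind %||% "", format(rec$source_event_magnitude %||% rec$magnitude),
          rec$sound_id %||% "", format(rec$gain %||% 1))
}

#' Log playback records to a session
#'
#' @param log A [open_session()] log.
#' @param records A data frame of playback records (`t_ms`, `sound_id`,
#'   `gain`, `source_event_magnitude` or `magnitude`, `kind`), e.g. from
#'   [play_events()].
#' @return The log, invisibly; one row is written (or buffered) per record.
#' @export
log_event <- function(log, records) {
  stopifnot(inherits(log, "session_log"))
  if (!isTRUE(log$open)) abort("session log is closed")
  if (nrow(records) == 0L) return(invisible(log))
  lines <- vapply(seq_len(nrow(records)),
                  function(i) record_to_line(as.list(records[i, ])), character(1))
  if (log$mode == "immediate") {
    cat(lines, file = log$path, sep = "\n", append = TRUE)
  } else {
    log$buffer <- c(log$buffer, as.list(lines))
  }
  invisible(log)
}

#' Close a session log, flushing any buffered rows
#'
#' @param log A session log.
#' @return The log path, invisibly.
#' @export
close_session <- function(log) {
  stopifnot(inherits(log, "session_log"))
  if (isTRUE(log$open) && log$mode == "buffered" && length(log$buffer) > 0L) {
    cat(unlist(log$buffer), file = log$path, sep = "\n", append = TRUE)
  }
  log$open <- FALSE
  log$buffer <- list()
  invisible(log$path)
}

#' Read a session log back
#'
#' Reconstructs the parameter blocks and the event rows of a log written by
#' [open_session()] / [log_event()].
#'
#' @param path Log file path.
#' @return A list with `$params` (tibble `block`, `key`, `value`) and
#'   `$events` (tibble `block`, `t_ms`, `iso_time`, `kind`, `magnitude`,
#'   `sound_id`, `gain`).
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  block <- 0L
  in_header <- FALSE
  params <- list(); events <- list()
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      if (!in_header) { block <- block + 1L; in_header <- TRUE }
      kv <- sub("^#\\s*", "", ln)
      eq <- regexpr("=", kv, fixed = TRUE)
      if (eq > 0) {
        params[[length(params) + 1L]] <- tibble(
          block = block, key = substr(kv, 1, eq - 1),
          value = substr(kv, eq + 1, nchar(kv)))
      }
    } else if (startsWith(ln, "t_ms,")) {
      in_header <- FALSE
    } else if (nzchar(ln)) {
      f <- strsplit(ln, ",", fixed = TRUE)[[1]]
      events[[length(events) + 1L]] <- tibble(
        block = block, t_ms = as.integer(f[1]), iso_time = f[2], kind = f[3],
        magnitude = as.numeric(f[4]), sound_id = f[5], gain = as.numeric(f[6]))
    }
  }
  list(
    params = if (length(params)) bind_rows(params)
             else tibble(block = integer(), key = character(), value = character()),
    events = if (length(events)) bind_rows(events)
             else tibble(block = integer(), t_ms = integer(), iso_time = character(),
                         kind = character(), magnitude = numeric(),
                         sound_id = character(), gain = numeric())
  )
}
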