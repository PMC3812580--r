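# Event-to-sound mapping and playback sinks. Detection events (thrusts,
# shakes) are mapped to sound triggers by kind and magnitude range; triggers
# are dispatched to a pluggable sink and every dispatch yields a playback
# record for the session log.

#' Define an event-to-sound mapping
#'
#' Rules associate an event kind (and optionally a magnitude range) with a
#' sound id and a gain. The gain curve turns event magnitude into playback
#' intensity: `"constant"` uses the rule's gain as is, `"linear"` maps the
#' rule's magnitude range linearly onto `gain_range` (so harder
#' manipulations play louder — the natural mapping for jerk), and
#' `"breakpoints"` interpolates a user table. Gains are always clipped to
#' `[0, 1]`.
#'
#' @param rules A data frame with columns `kind`, `sound_id` and optionally
#'   `min_magnitude` (default 0), `max_magnitude` (default `Inf`), `gain`
#'   (default 1). Magnitude ranges within one kind must not overlap.
#' @param gain_curve `"constant"`, `"linear"` or `"breakpoints"`.
#' @param gain_range Output gain range for the linear curve. Default `c(0, 1)`.
#' @param breakpoints For the breakpoint curve: a data frame `magnitude`,
#'   `gain` with nondecreasing gain.
#' @return A list of class `sound_mapping`.
#' @examples
#' sound_mapping(tibble::tibble(kind = "thrust", sound_id = "snare", gain = 1))
#' @export
sound_mapping <- function(rules, gain_curve = c("constant", "linear", "breakpoints"),
                          gain_range = c(0, 1), breakpoints = NULL) {
  gain_curve <- match.arg(gain_curve)
  if (!all(c("kind", "sound_id") %in% names(rules))) {
    abort("rules need columns kind and sound_id")
  }
  rules <- as_tibble(rules)
  if (!"min_magnitude" %in% names(rules)) rules$min_magnitude <- 0
  if (!"max_magnitude" %in% names(rules)) rules$max_magnitude <- Inf
  if (!"gain" %in% names(rules)) rules$gain <- 1
  if (any(rules$gain < 0 | rules$gain > 1)) abort("rule gains must lie in [0, 1]")
  if (any(rules$min_magnitude >= rules$max_magnitude)) {
    abort("each rule needs min_magnitude < max_magnitude")
  }
  for (k in unique(rules$kind)) {
    r <- rules[rules$kind == k, ]
    r <- r[order(r$min_magnitude), ]
    if (nrow(r) > 1L && any(r$min_magnitude[-1] < r$max_magnitude[-nrow(r)])) {
      abort(paste0("overlapping magnitude ranges for kind '", k, "'"))
    }
  }
  if (gain_curve == "linear" && any(!is.finite(rules$max_magnitude))) {
    abort("the linear gain curve needs finite max_magnitude in every rule")
  }
  if (gain_curve == "breakpoints") {
    if (is.null(breakpoints) || !all(c("magnitude", "gain") %in% names(breakpoints))) {
      abort("breakpoint curve needs a breakpoints table with magnitude and gain")
    }
    if (is.unsorted(breakpoints$magnitude, strictly = TRUE)) {
      abort("breakpoint magnitudes must be strictly increasing")
    }
    if (is.unsorted(breakpoints$gain)) abort("breakpoint gains must be nondecreasing")
  }
  structure(list(rules = rules, gain_curve = gain_curve,
                 gain_range = gain_range, breakpoints = breakpoints),
            class = "sound_mapping")
}

#' Map detection events to sound triggers
#'
#' Deterministic rule lookup by event kind and magnitude; an event whose
#' kind or magnitude no rule covers is an error (a mapping is expected to
#' cover everything its detector can emit).
#'
#' @param events A tibble of detection events (`t_ms`, `kind`, `magnitude`),
#'   e.g. from [detect_thrusts()] or [detect_shakes()].
#' @param mapping A [sound_mapping()].
#' @return A tibble of triggers: `t_ms`, `kind`, `magnitude`, `sound_id`,
#'   `gain`.
#' @export
map_events <- function(events, mapping) {
  stopifnot(inherits(mapping, "sound_mapping"))
  if (nrow(events) == 0L) {
    return(tibble(t_ms = integer(), kind = character(), magnitude = numeric(),
                  sound_id = character(), gain = numeric()))
  }
  rules <- mapping$rules
  hit <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    e <- events[i, ]
    r <- rules[rules$kind == e$kind &
                 rules$min_magnitude <= e$magnitude &
                 e$magnitude < rules$max_magnitude, ]
    if (nrow(r) == 0L) {
      abort(paste0("no mapping rule covers kind '", e$kind,
                   "' at magnitude ", format(e$magnitude)))
    }
    r <- r[1, ]
    g <- switch(mapping$gain_curve,
      constant = r$gain,
      linear = {
        frac <- (e$magnitude - r$min_magnitude) / (r$max_magnitude - r$min_magnitude)
        mapping$gain_range[1] + frac * diff(mapping$gain_range)
      },
      breakpoints = approx(mapping$breakpoints$magnitude, mapping$breakpoints$gain,
                           xout = e$magnitude, rule = 2)$y
    )
    tibble(t_ms = e$t_ms, kind = e$kind, magnitude = e$magnitude,
           sound_id = r$sound_id, gain = min(max(g, 0), 1))
  })
  hit
}

#' Playback sinks
#'
#' A sink receives sound triggers. `null_sink()` swallows them (tests,
#' dry runs); `file_sink(path)` appends each playback record to a CSV file.
#' Both honour the same contract: one playback record per trigger.
#'
#' @param path File the file sink appends to (created with a header line if
#'   absent).
#' @return An environment of class `playback_sink`.
#' @rdname playback_sink
#' @export
null_sink <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "null"; e$open <- TRUE
  class(e) <- "playback_sink"
  e
}

#' @rdname playback_sink
#' @export
file_sink <- function(path) {
  if (!file.exists(path)) {
    writeLines("t_ms,sound_id,gain,source_event_magnitude", path)
  }
  e <- new.env(parent = emptyenv())
  e$type <- "file"; e$path <- path; e$open <- TRUE
  class(e) <- "playback_sink"
  e
}

#' @rdname playback_sink
#' @param sink A playback sink.
#' @export
close_sink <- function(sink) {
  sink$open <- FALSE
  invisible(sink)
}

#' Dispatch sound triggers to a sink
#'
#' Sends each trigger to the sink and returns one playback record per
#' trigger, timestamped at the trigger time. Dispatch latency (wall-clock
#' milliseconds spent per trigger) is measured and attached as attribute
#' `latency_ms`.
#'
#' @param triggers Output of [map_events()].
#' @param sink A playback sink; default [null_sink()].
#' @return A tibble of playback records: `t_ms`, `sound_id`, `gain`,
#'   `source_event_magnitude`, `kind`.
#' @export
play_events <- function(triggers, sink = null_sink()) {
  stopifnot(inherits(sink, "playback_sink"))
  if (!isTRUE(sink$open)) abort("playback sink is closed")
  t0 <- Sys.time()
  records <- tibble(
    t_ms = triggers$t_ms,
    sound_id = triggers$sound_id,
    gain = triggers$gain,
    source_event_magnitude = triggers$magnitude,
    kind = triggers$kind
  )
  if (sink$type == "file" && nrow(records) > 0L) {
    lines <- sprintf("%d,%s,%s,%s", records$t_ms, records$sound_id,
                     format(records$gain), format(records$source_event_magnitude))
    cat(lines, file = sink$path, sep = "\n", append = TRUE)
  }
  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000
  attr(records, "latency_ms") <- if (nrow(records)) elapsed / nrow(records) else 0
  records
}
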