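# Wired pipeline: channel summing, noise gating, two-stage thrust detection,
# serial-line parsing.

#' Configuration for the wired strain detector
#'
#' Holds the thresholds and timing constants of the wired pipeline. The
#' defaults are the deployed values: readings below the 500-count noise gate
#' are ignored during recording, a candidate event opens when the four-channel
#' sum exceeds 1000 counts, it is confirmed if the sum re-read 5 ms later
#' exceeds 1765 counts (the lower 95% confidence bound of the thrust profile
#' at 5 ms), and a confirmed event imposes a 300 ms refractory period.
#'
#' @param noise_gate Counts; sums at or below this are dropped in
#'   recording/calibration mode. Default 500.
#' @param stage1_threshold Counts; a frame whose sum exceeds this opens a
#'   detection candidate. Default 1000.
#' @param stage2_threshold Counts; the re-read sum must exceed this to emit an
#'   event. Default 1765.
#' @param stage2_delay_ms Milliseconds between the candidate frame and the
#'   confirmation re-read. Default 5.
#' @param refractory_ms Milliseconds after an emitted event during which no
#'   new candidate may open. Default 300.
#' @param min_sample_interval_ms Minimum spacing a valid stream must keep
#'   between consecutive frames. Default 1.
#'
#' @return A list of class `strain_config`.
#' @examples
#' strain_config()
#' strain_config(stage2_threshold = 1500)
#' @export
strain_config <- function(noise_gate = 500L,
                          stage1_threshold = 1000L,
                          stage2_threshold = 1765L,
                          stage2_delay_ms = 5L,
                          refractory_ms = 300L,
                          min_sample_interval_ms = 1L) {
  cfg <- list(
    noise_gate = as.integer(noise_gate),
    stage1_threshold = as.integer(stage1_threshold),
    stage2_threshold = as.integer(stage2_threshold),
    stage2_delay_ms = as.integer(stage2_delay_ms),
    refractory_ms = as.integer(refractory_ms),
    min_sample_interval_ms = as.integer(min_sample_interval_ms)
  )
  if (cfg$noise_gate < 0 || cfg$noise_gate > cfg$stage1_threshold ||
      cfg$stage1_threshold > cfg$stage2_threshold ||
      cfg$stage2_threshold > 4092L) {
    abort("strain_config requires 0 <= noise_gate <= stage1_threshold <= stage2_threshold <= 4092")
  }
  if (cfg$stage2_delay_ms <= 0L) abort("stage2_delay_ms must be > 0")
  if (cfg$refractory_ms < 0L) abort("refractory_ms must be >= 0")
  structure(cfg, class = "strain_config")
}

#' @export
print.strain_config <- function(x, ...) {
  cat("<strain_config>\n")
  for (nm in names(x)) cat(" ", nm, "=", x[[nm]], "\n")
  invisible(x)
}

channel_cols <- c("s1", "s2", "s3", "s4")

validate_strain_frames <- function(frames, cfg = NULL) {
  if (!all(channel_cols %in% names(frames)) || !"t_ms" %in% names(frames)) {
    abort("strain frames need columns t_ms, s1, s2, s3, s4")
  }
  ch <- as.matrix(frames[channel_cols])
  if (anyNA(ch) || any(ch < 0) || any(ch > 1023)) {
    abort("invalid strain frame: channel values must lie in [0, 1023]")
  }
  if (nrow(frames) > 1L) {
    dt <- diff(frames$t_ms)
    if (any(dt <= 0)) abort("strain frame timestamps must be strictly increasing")
    if (!is.null(cfg) && any(dt < cfg$min_sample_interval_ms)) {
      abort("strain frames closer than min_sample_interval_ms")
    }
  }
  invisible(frames)
}

#' Sum the four strain channels of each frame
#'
#' The microcontroller reduces every 4-channel frame to the sum of its
#' readings; with 10-bit channels the sum is bounded by 4092. Frames with any
#' channel outside `[0, 1023]` are rejected.
#'
#' @param frames A data frame with columns `t_ms`, `s1`..`s4`.
#' @return The input as a tibble with an added integer `sum` column.
#' @examples
#' sum_frames(tibble::tibble(t_ms = 0, s1 = 100, s2 = 200, s3 = 300, s4 = 400))
#' @export
sum_frames <- function(frames) {
  validate_strain_frames(frames)
  frames <- as_tibble(frames)
  frames$sum <- as.integer(rowSums(frames[channel_cols]))
  frames
}

#' Apply the recording-mode noise gate
#'
#' Flags which summed readings pass the gate: a reading passes iff it is
#' strictly greater than `cfg$noise_gate`. Gentle touching of the surface
#' produces sums up to about 500 counts, so the default gate of 500 silences
#' it.
#'
#' @param readings A data frame with a `sum` column (e.g. from
#'   [sum_frames()]), or a bare numeric vector of sums.
#' @param cfg A [strain_config()].
#' @return For a data frame input, a tibble with added logical `pass`; for a
#'   vector, a logical vector.
#' @examples
#' apply_noise_gate(c(499, 500, 501))
#' @export
apply_noise_gate <- function(readings, cfg = strain_config()) {
  if (is.data.frame(readings)) {
    if (!"sum" %in% names(readings)) abort("readings need a 'sum' column")
    readings <- as_tibble(readings)
    readings$pass <- readings$sum > cfg$noise_gate
    readings
  } else {
    readings > cfg$noise_gate
  }
}

# Normalise detector input: frames (t_ms + 4 channels) or pre-summed
# (t_ms + sum) are accepted interchangeably.
as_summed_stream <- function(stream, cfg) {
  if (!is.data.frame(stream)) abort("stream must be a data frame")
  if (all(channel_cols %in% names(stream))) {
    validate_strain_frames(stream, cfg)
    stream <- sum_frames(stream)
  }
  if (!all(c("t_ms", "sum") %in% names(stream))) {
    abort("stream needs columns t_ms,s1..s4 or t_ms,sum")
  }
  if (nrow(stream) > 1L && any(diff(stream$t_ms) <= 0)) {
    abort("stream timestamps must be strictly increasing")
  }
  as_tibble(stream)[c("t_ms", "sum")]
}

#' Detect thrust events with the two-stage threshold rule
#'
#' Scans a strain stream for thrusts. A frame at time `t` whose sum exceeds
#' `stage1_threshold` opens a candidate; the detector then looks at the
#' nearest frame at or after `t + stage2_delay_ms` (abandoning the candidate
#' if none arrives within twice the delay) and emits an event iff that
#' second-stage sum exceeds `stage2_threshold`. The event carries the
#' second-stage sum as its magnitude and is stamped at `t + stage2_delay_ms`.
#' After an emitted event no candidate may open for `refractory_ms`,
#' measured from the triggering (stage-1) frame, so a single manipulation
#' yields a single sound. Candidates that fail confirmation impose no
#' refractory.
#'
#' @param stream A data frame of frames (`t_ms`, `s1`..`s4`) or pre-summed
#'   readings (`t_ms`, `sum`).
#' @param cfg A [strain_config()].
#' @return A tibble of events: `t_ms` (emission time), `kind` (`"thrust"`),
#'   `magnitude` (second-stage sum), `trigger_t_ms` (stage-1 frame time).
#' @examples
#' pulse <- gen_strain_pulse("thrust", seed = 1)
#' detect_thrusts(pulse)
#' @export
detect_thrusts <- function(stream, cfg = strain_config()) {
  empty <- tibble(t_ms = integer(), kind = character(),
                  magnitude = numeric(), trigger_t_ms = integer())
  if (is.data.frame(stream) && nrow(stream) == 0L) return(empty)
  s <- as_summed_stream(stream, cfg)
  t <- s$t_ms
  v <- s$sum
  n <- length(t)
  last_trigger <- -Inf
  out_t <- integer(0); out_m <- numeric(0); out_trig <- integer(0)
  j <- 1L
  for (i in seq_len(n)) {
    if (v[i] <= cfg$stage1_threshold) next
    if (t[i] - last_trigger < cfg$refractory_ms) next
    # nearest frame at or after t + delay; abandon if it is late by > delay
    target <- t[i] + cfg$stage2_delay_ms
    j <- i
    while (j <= n && t[j] < target) j <- j + 1L
    if (j > n || t[j] > t[i] + 2L * cfg$stage2_delay_ms) next
    if (v[j] > cfg$stage2_threshold) {
      out_t <- c(out_t, t[i] + cfg$stage2_delay_ms)
      out_m <- c(out_m, v[j])
      out_trig <- c(out_trig, t[i])
      last_trigger <- t[i]
    }
  }
  tibble(t_ms = as.integer(out_t), kind = rep("thrust", length(out_t)),
         magnitude = as.numeric(out_m), trigger_t_ms = as.integer(out_trig))
}

#' Parse serial lines carrying summed readings
#'
#' The microcontroller transmits each confirmed sum as an ASCII decimal
#' integer terminated by a newline. Transmission can corrupt bytes, so a line
#' is accepted only if, after stripping surrounding whitespace, it consists
#' solely of decimal digits; anything else is rejected as data (not an
#' error).
#'
#' @param lines Character vector of received lines.
#' @return An integer vector the same length as `lines`; rejected lines map
#'   to `NA`.
#' @examples
#' parse_serial_line(c("2100\n", "21x0", "", " 42 "))
#' @export
parse_serial_line <- function(lines) {
  stripped <- gsub("^[ \t\r\n]+|[ \t\r\n]+$", "", lines)
  ok <- grepl("^[0-9]+$", stripped)
  out <- rep(NA_integer_, length(lines))
  out[ok] <- as.integer(stripped[ok])
  out
}
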