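# Wireless pipeline: per-axis acceleration deltas, Euclidean-norm jerk,
# activation threshold with a continuously reset debounce timer.

#' Configuration for the wireless shake detector
#'
#' @param activation_threshold Jerk (raw accelerometer counts) above which a
#'   sample counts as an activation. The deployed device exposes this as a
#'   live slider; the default of 30 counts sits well above walking jerk and
#'   well below shaking jerk for the synthetic regimes shipped with the
#'   package.
#' @param refractory_ms Debounce window in milliseconds: an activation is
#'   sonified only if at least this long has passed since the previous
#'   activation (sonified or not). Default 300.
#' @param cadence_ms Nominal sampling period of the accelerometer. Default
#'   10 (the device updates every 10 ms at 8 bit per axis).
#' @param jitter_ms Allowed deviation from the nominal cadence before a
#'   stream is rejected. Default 2.
#' @return A list of class `motion_config`.
#' @examples
#' motion_config()
#' @export
motion_config <- function(activation_threshold = 30,
                          refractory_ms = 300L,
                          cadence_ms = 10L,
                          jitter_ms = 2L) {
  if (activation_threshold <= 0) abort("activation_threshold must be > 0")
  if (refractory_ms < 0) abort("refractory_ms must be >= 0")
  structure(list(
    activation_threshold = activation_threshold,
    refractory_ms = as.integer(refractory_ms),
    cadence_ms = as.integer(cadence_ms),
    jitter_ms = as.integer(jitter_ms)
  ), class = "motion_config")
}

#' @export
print.motion_config <- function(x, ...) {
  cat("<motion_config>\n")
  for (nm in names(x)) cat(" ", nm, "=", x[[nm]], "\n")
  invisible(x)
}

axis_cols <- c("ax", "ay", "az")

validate_motion_frames <- function(frames, cfg = NULL) {
  if (!all(c("t_ms", axis_cols) %in% names(frames))) {
    abort("motion frames need columns t_ms, ax, ay, az")
  }
  a <- as.matrix(frames[axis_cols])
  if (anyNA(a) || any(a < 0) || any(a > 255)) {
    abort("invalid motion frame: axis values must lie in [0, 255]")
  }
  if (nrow(frames) > 1L) {
    dt <- diff(frames$t_ms)
    if (any(dt <= 0)) abort("motion frame timestamps must be strictly increasing")
    if (!is.null(cfg) && any(abs(dt - cfg$cadence_ms) > cfg$jitter_ms)) {
      abort("motion stream violates the nominal sampling cadence")
    }
  }
  invisible(frames)
}

#' Per-axis acceleration differences between two frames
#'
#' @param prev,cur Single-row data frames (or named lists) with `t_ms`,
#'   `ax`, `ay`, `az`. `cur` must be later than `prev`.
#' @return A named numeric vector `c(dx, dy, dz)` of `cur - prev` per axis.
#'   Any constant offset common to both frames (e.g. the gravity component
#'   on one axis, or a systematic sensor bias) cancels.
#' @examples
#' axis_deltas(list(t_ms = 0, ax = 128, ay = 128, az = 170),
#'             list(t_ms = 10, ax = 131, ay = 128, az = 170))
#' @export
axis_deltas <- function(prev, cur) {
  if (cur$t_ms <= prev$t_ms) abort("cur must be later than prev")
  c(dx = cur$ax - prev$ax, dy = cur$ay - prev$ay, dz = cur$az - prev$az)
}

#' Euclidean-norm jerk of per-axis deltas
#'
#' The change in acceleration between consecutive samples, collapsed to one
#' nonnegative number: `sqrt(dx^2 + dy^2 + dz^2)`.
#'
#' @param dx,dy,dz Numeric vectors of per-axis deltas (recycled together).
#' @return Numeric vector of jerk values.
#' @examples
#' jerk_norm(3, 4, 0)  # 5
#' @export
jerk_norm <- function(dx, dy, dz) sqrt(dx^2 + dy^2 + dz^2)

#' Add delta and jerk columns to a motion stream
#'
#' @param frames A data frame with `t_ms`, `ax`, `ay`, `az`.
#' @return The stream as a tibble with added `dax`, `day`, `daz`, `jerk`;
#'   the first frame has all four set to 0 (jerk is undefined there and the
#'   detector treats it as silent).
#' @export
add_jerk <- function(frames) {
  validate_motion_frames(frames)
  frames <- as_tibble(frames)
  frames$dax <- c(0, diff(frames$ax))
  frames$day <- c(0, diff(frames$ay))
  frames$daz <- c(0, diff(frames$az))
  frames$jerk <- jerk_norm(frames$dax, frames$day, frames$daz)
  frames
}

#' Detect shake events with a continuously reset debounce timer
#'
#' Every sample whose jerk exceeds `activation_threshold` is an *activation*.
#' An activation is sonified (emitted as an event) only if at least
#' `refractory_ms` has elapsed since the previous activation — and every
#' activation, sonified or suppressed, resets that timer. Consequently a
#' dense burst of activations produces exactly one event (its first), and a
#' sustained shake stays silent until a quiet period has elapsed.
#'
#' @param stream A data frame with `t_ms`, `ax`, `ay`, `az`.
#' @param cfg A [motion_config()].
#' @return A tibble of events: `t_ms`, `kind` (`"shake"`), `magnitude`
#'   (jerk at the activation).
#' @examples
#' shake <- gen_accel_stream(accel_regime("shake"), seed = 1)
#' detect_shakes(shake)
#' @export
detect_shakes <- function(stream, cfg = motion_config()) {
  empty <- tibble(t_ms = integer(), kind = character(), magnitude = numeric())
  if (nrow(stream) < 2L) return(empty)
  validate_motion_frames(stream, cfg)
  s <- add_jerk(stream)
  act <- which(s$jerk > cfg$activation_threshold & seq_len(nrow(s)) > 1L)
  if (length(act) == 0L) return(empty)
  last_act <- -Inf
  keep <- logical(length(act))
  for (k in seq_along(act)) {
    t <- s$t_ms[act[k]]
    keep[k] <- (t - last_act) >= cfg$refractory_ms
    last_act <- t  # every activation resets the timer
  }
  tibble(t_ms = as.integer(s$t_ms[act[keep]]),
         kind = rep("shake", sum(keep)),
         magnitude = s$jerk[act[keep]])
}
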