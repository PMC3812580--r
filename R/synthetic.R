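# Seeded generators for every input the pipelines consume: strain pulses by
# manipulation type, drop-calibration sessions, and rest/walk/shake
# acceleration streams. All tests run hardware-free on these.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Summed-signal envelopes (ms -> counts), piecewise linear. The defining
# features: a thrust exceeds the 1000-count stage-1 level at onset and the
# 1765-count stage-2 level at 5 ms, with a secondary rise at 70-95 ms; a hit
# matches the thrust's onset magnitude but has decayed below stage 2 by
# 5 ms; a tap peaks between the noise gate and stage 1; a touch stays below
# the 500-count noise gate throughout.
pulse_envelopes <- list(
  thrust = list(t = c(0, 3, 5, 8, 15, 40, 70, 85, 95, 120),
                v = c(2100, 1850, 1900, 1500, 1050, 520, 1300, 1450, 700, 0)),
  hit    = list(t = c(0, 5, 12, 30, 60, 120),
                v = c(2100, 1200, 950, 400, 200, 0)),
  tap    = list(t = c(0, 2, 6, 20, 40, 120),
                v = c(650, 800, 600, 250, 0, 0)),
  touch  = list(t = c(0, 3, 10, 40, 120),
                v = c(250, 400, 300, 100, 0))
)

check_pulse_envelope <- function(kind, env_fun) {
  bad <- switch(kind,
    thrust = env_fun(0) <= 1000 || env_fun(5) <= 1765,
    hit    = env_fun(0) <= 1000 || env_fun(5) >= 1765 || max(env_fun(5:120)) >= 1765,
    tap    = {e <- env_fun(0:120); max(e) >= 1000 || max(e) <= 500},
    touch  = max(env_fun(0:120)) >= 500,
    abort(paste0("unknown pulse kind '", kind, "'"))
  )
  if (bad) abort(paste0("pulse envelope violates the defining inequalities of kind '", kind, "'"))
}

#' Generate one synthetic strain pulse
#'
#' Emulates the summed four-channel signature of one manipulation of the
#' wired surface. Four kinds are modelled, ordered by peak magnitude
#' touch < tap < hit <= thrust; only a thrust still exceeds the stage-2
#' threshold 5 ms after onset, which is exactly what the two-stage detector
#' exploits. The summed envelope is split equally over the four channels and
#' independent Gaussian noise is added per channel before clipping to the
#' 10-bit range.
#'
#' @param kind One of `"touch"`, `"tap"`, `"hit"`, `"thrust"`.
#' @param peak_sum Optional peak of the summed envelope, counts; the default
#'   envelope is rescaled to it. Rescaling that breaks the kind's defining
#'   inequalities is an error.
#' @param noise_sd Per-channel noise standard deviation, counts. Default 3.
#' @param start_ms Timestamp of the first frame. Default 0.
#' @param duration_ms Pulse length; frames are generated at a 1 ms cadence
#'   over `[0, duration_ms]`. Default 120.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A tibble of strain frames: `t_ms`, `s1`..`s4`.
#' @examples
#' nrow(gen_strain_pulse("thrust", seed = 1))
#' @export
gen_strain_pulse <- function(kind, peak_sum = NULL, noise_sd = 3,
                             start_ms = 0L, duration_ms = 120L, seed = NULL) {
  kind <- match.arg(kind, names(pulse_envelopes))
  env <- pulse_envelopes[[kind]]
  scale <- if (is.null(peak_sum)) 1 else peak_sum / max(env$v)
  env_fun <- function(t) approx(env$t, env$v * scale, xout = pmin(t, max(env$t)),
                                rule = 2)$y
  check_pulse_envelope(kind, env_fun)
  with_seed(seed, {
    t_rel <- 0:duration_ms
    e <- env_fun(t_rel)
    ch <- vapply(1:4, function(k) {
      pmin(pmax(round(e / 4 + rnorm(length(e), 0, noise_sd)), 0), 1023)
    }, numeric(length(t_rel)))
    tibble(t_ms = as.integer(start_ms + t_rel),
           s1 = as.integer(ch[, 1]), s2 = as.integer(ch[, 2]),
           s3 = as.integer(ch[, 3]), s4 = as.integer(ch[, 4]))
  })
}

#' Generate a train of strain pulses
#'
#' Concatenates seeded pulses at a fixed onset spacing; pulses longer than
#' the spacing are truncated so frames never overlap in time. Useful for
#' stress-testing the detector's refractory behaviour.
#'
#' @param kinds Character vector of pulse kinds, one per pulse (recycled if
#'   a single kind is given with `n`).
#' @param n Number of pulses when `kinds` has length 1.
#' @param spacing_ms Onset-to-onset spacing, ms. Default 100.
#' @param noise_sd,seed Passed to [gen_strain_pulse()]; each pulse is seeded
#'   with `seed + i`.
#' @return A tibble of strain frames covering the whole train.
#' @export
gen_pulse_train <- function(kinds, n = length(kinds), spacing_ms = 100L,
                            noise_sd = 3, seed = NULL) {
  if (length(kinds) == 1L) kinds <- rep(kinds, n)
  purrr::map_dfr(seq_along(kinds), function(i) {
    p <- gen_strain_pulse(kinds[i], noise_sd = noise_sd,
                          start_ms = (i - 1L) * spacing_ms,
                          seed = if (is.null(seed)) NULL else seed + i)
    p[p$t_ms < i * spacing_ms, ]
  })
}

#' Residual noise for a target calibration fit quality
#'
#' Given the fixed drop design (heights and repetitions) and the nominal
#' slope, returns the between-trial residual standard deviation for which
#' the expected adjusted R-squared of the calibration regression equals
#' `target_adj_r2`, via R^2 = SS_model / (SS_model + (n-2) sigma^2).
#'
#' @param target_adj_r2 Target adjusted R-squared. Default 0.56, the fit
#'   quality observed on the deployed device.
#' @param heights_cm Design heights. Default 20--180 cm in 20 cm steps.
#' @param reps Drops per height. Default 5.
#' @param slope Counts per cm. Default 3.
#' @return Residual standard deviation in counts.
#' @export
drop_noise_sd <- function(target_adj_r2 = 0.56,
                          heights_cm = seq(20, 180, by = 20),
                          reps = 5L, slope = 3) {
  d <- rep(heights_cm, each = reps)
  n <- length(d)
  r2 <- 1 - (1 - target_adj_r2) * (n - 2) / (n - 1)
  ss_model <- slope^2 * sum((d - mean(d))^2)
  sqrt(ss_model * (1 - r2) / (r2 * (n - 2)))
}

# fixed zero-mean within-trial shape: impact decay whose first-10 mean is 0,
# so the trial feature recovers the trial mean exactly in the noiseless limit
trial_shape <- function(n) {
  w10 <- c(500, 350, 220, 110, 20, -80, -170, -250, -320, -380)
  w <- c(w10, seq(-410, by = -15, length.out = max(0, n - 10)))
  w[seq_len(n)]
}

#' Generate a synthetic drop-calibration session
#'
#' Emulates the calibration protocol: a weight dropped from each height in
#' `heights_cm`, `reps` times per height (9 x 5 = 45 trials by default),
#' with consecutive drops separated by more than 2 s. Each trial's
#' first-10-sample mean is `intercept + slope * height + N(0, residual_sd)`;
#' within a trial, samples follow a fixed zero-mean decay shape so the
#' noiseless limit reproduces the calibration line exactly. With probability
#' `ricochet_prob` a trial is followed by one or two rebound "ricochet"
#' echoes 600--900 ms after the preceding reading — inside the window that
#' segmentation must discard.
#'
#' @param heights_cm Drop heights. Default 20--180 cm by 20.
#' @param reps Drops per height. Default 5.
#' @param residual_sd Between-trial noise, counts; default derived from a
#'   target adjusted R-squared of 0.56 via [drop_noise_sd()]. Use 0 for the
#'   noiseless limit.
#' @param samples_per_trial Readings per trial. Default 15 (the cap used in
#'   analysis is 10, so default trials exceed it).
#' @param sample_gap_ms Within-trial sample spacing, ms. Default 40.
#' @param ricochet_prob Probability a trial is followed by echoes. Default 0.7.
#' @param intercept,slope Calibration-line parameters, counts and counts/cm.
#' @param seed Optional integer seed.
#' @return A list with `$readings` (tibble `t_ms`, `sum`; sums are analogue
#'   counts, unquantised), `$truth` (tibble `trial`, `height_cm`,
#'   `onset_ms`) and `$n_echoes` (echo readings injected).
#' @examples
#' s <- gen_drop_session(seed = 1)
#' nrow(s$truth)  # 45
#' @export
gen_drop_session <- function(heights_cm = seq(20, 180, by = 20), reps = 5L,
                             residual_sd = drop_noise_sd(0.56, heights_cm, reps),
                             samples_per_trial = 15L, sample_gap_ms = 40L,
                             ricochet_prob = 0.7, intercept = 1208.29,
                             slope = 3, seed = NULL) {
  if (any(heights_cm <= 0)) abort("heights must be positive")
  heights <- rep(heights_cm, each = reps)
  if (length(heights) == 0L) {
    return(list(readings = tibble(t_ms = integer(), sum = numeric()),
                truth = tibble(trial = integer(), height_cm = numeric(),
                               onset_ms = integer()),
                n_echoes = 0L))
  }
  with_seed(seed, {
    shape <- trial_shape(samples_per_trial)
    t_cursor <- 0
    rows_t <- list(); rows_v <- list()
    truth <- vector("list", length(heights))
    n_echoes <- 0L
    for (i in seq_along(heights)) {
      mu <- intercept + slope * heights[i] + rnorm(1, 0, residual_sd)
      tt <- t_cursor + (seq_len(samples_per_trial) - 1L) * sample_gap_ms
      vv <- pmax(mu + shape, 1)
      truth[[i]] <- tibble(trial = i, height_cm = heights[i],
                           onset_ms = as.integer(tt[1]))
      last <- tt[length(tt)]
      if (runif(1) < ricochet_prob) {
        for (k in seq_len(sample.int(2L, 1L))) {
          last <- last + round(runif(1, 600, 900))
          tt <- c(tt, last)
          vv <- c(vv, round(runif(1, 520, 900)))
          n_echoes <- n_echoes + 1L
        }
      }
      rows_t[[i]] <- tt
      rows_v[[i]] <- vv
      t_cursor <- last + 2000 + round(runif(1, 50, 500))
    }
    list(readings = tibble(t_ms = as.integer(unlist(rows_t)),
                           sum = unlist(rows_v)),
         truth = bind_rows(truth),
         n_echoes = n_echoes)
  })
}

#' Describe an acceleration regime
#'
#' Parameter bundle for [gen_accel_stream()]. `rest` is the device lying
#' still (zero-g baseline plus sensor noise, gravity offsetting one axis);
#' `walk` adds a slow locomotion sinusoid whose jerk stays well below the
#' activation threshold; `shake` superimposes short high-jerk bursts at the
#' given times.
#'
#' @param mode `"rest"`, `"walk"` or `"shake"`.
#' @param duration_ms Stream length. Default 10000.
#' @param gravity_axis Axis carrying the gravity offset (`"ax"`, `"ay"`,
#'   `"az"`). Default `"az"`.
#' @param gravity_offset Counts added to the gravity axis; about 42 counts
#'   per g for the 8-bit +/-3 g encoding (zero g near 128). Default 42.
#' @param walk_period_ms,walk_amp Locomotion sinusoid period and amplitude
#'   (counts). Defaults 800 ms and 12 counts.
#' @param shake_times_ms Burst onset times. Default 1, 2 and 3 s (three
#'   shakes in succession).
#' @param shake_amp Burst amplitude, counts. Default 60.
#' @param shake_len_ms Burst length. Default 60 ms.
#' @param noise_sd Per-axis sensor noise, counts. Default 1.
#' @return A list of class `accel_regime`.
#' @export
accel_regime <- function(mode = c("rest", "walk", "shake"),
                         duration_ms = 10000L, gravity_axis = "az",
                         gravity_offset = 42, walk_period_ms = 800,
                         walk_amp = 12, shake_times_ms = c(1000, 2000, 3000),
                         shake_amp = 60, shake_len_ms = 60, noise_sd = 1) {
  mode <- match.arg(mode)
  gravity_axis <- match.arg(gravity_axis, c("ax", "ay", "az"))
  structure(list(mode = mode, duration_ms = as.integer(duration_ms),
                 gravity_axis = gravity_axis, gravity_offset = gravity_offset,
                 walk_period_ms = walk_period_ms, walk_amp = walk_amp,
                 shake_times_ms = shake_times_ms, shake_amp = shake_amp,
                 shake_len_ms = shake_len_ms, noise_sd = noise_sd),
            class = "accel_regime")
}

#' Generate a synthetic acceleration stream
#'
#' Frames at the nominal 10 ms cadence, 8-bit per axis, zero g near 128
#' counts with gravity offsetting one axis — so rest and walk differ in
#' absolute acceleration but barely in jerk, while shake bursts produce
#' large sample-to-sample deltas on all axes.
#'
#' @param regime An [accel_regime()].
#' @param seed Optional integer seed.
#' @return A tibble of motion frames: `t_ms`, `ax`, `ay`, `az`.
#' @examples
#' detect_shakes(gen_accel_stream(accel_regime("walk"), seed = 1))
#' @export
gen_accel_stream <- function(regime, seed = NULL) {
  stopifnot(inherits(regime, "accel_regime"))
  with_seed(seed, {
    t <- seq(0L, regime$duration_ms, by = 10L)
    n <- length(t)
    base <- matrix(128, n, 3, dimnames = list(NULL, axis_cols))
    base[, regime$gravity_axis] <- base[, regime$gravity_axis] + regime$gravity_offset
    if (regime$mode == "walk") {
      base[, "ax"] <- base[, "ax"] +
        regime$walk_amp * sin(2 * pi * t / regime$walk_period_ms)
    }
    if (regime$mode == "shake") {
      for (b in regime$shake_times_ms) {
        idx <- which(t >= b & t < b + regime$shake_len_ms)
        sgn <- rep_len(c(1, -1), length(idx))
        base[idx, ] <- base[idx, ] + regime$shake_amp * sgn
      }
    }
    base <- base + matrix(rnorm(n * 3, 0, regime$noise_sd), n, 3)
    base <- pmin(pmax(round(base), 0), 255)
    tibble(t_ms = as.integer(t), ax = as.integer(base[, 1]),
           ay = as.integer(base[, 2]), az = as.integer(base[, 3]))
  })
}
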