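# Drop-test calibration: trial segmentation with ricochet rejection,
# first-10-sample features, OLS of mean reading on fall height, and
# onset-aligned strain-type profiles with per-bin Welch tests.

#' Segment a gated reading stream into drop trials
#'
#' Drops in the calibration protocol are separated by at least 2 s, while
#' readings within one impact arrive much closer together; the surface's
#' rebound also produces delayed "ricochet" readings. Segmentation walks the
#' time-ordered readings and classifies each by its gap to the immediately
#' preceding reading: a gap of at least `onset_gap_ms` (or stream start)
#' opens a new trial; a gap of at most `ricochet_gap_ms` continues whatever
#' the previous reading belonged to (trial, or a discarded ricochet
#' cluster); anything in between is discarded as ricochet stress.
#'
#' @param readings A data frame with `t_ms` and `sum`, time-ordered, already
#'   above the noise gate.
#' @param onset_gap_ms Minimum silence before a new trial. Default 2000.
#' @param ricochet_gap_ms Maximum within-trial gap. Default 500.
#' @return A tibble `t_ms`, `sum`, `trial` (integer trial id, `NA` for
#'   discarded readings), with attribute `n_discarded`.
#' @examples
#' s <- gen_drop_session(seed = 1)
#' seg <- segment_trials(s$readings)
#' max(seg$trial, na.rm = TRUE)
#' @export
segment_trials <- function(readings, onset_gap_ms = 2000L, ricochet_gap_ms = 500L) {
  if (nrow(readings) == 0L) {
    out <- tibble(t_ms = integer(), sum = numeric(), trial = integer())
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  if (!all(c("t_ms", "sum") %in% names(readings))) {
    abort("readings need columns t_ms and sum")
  }
  t <- readings$t_ms
  if (is.unsorted(t, strictly = TRUE)) abort("readings must be strictly time-ordered")
  n <- length(t)
  trial <- rep(NA_integer_, n)
  cur <- 0L
  in_trial <- FALSE
  for (i in seq_len(n)) {
    gap <- if (i == 1L) Inf else t[i] - t[i - 1L]
    if (gap >= onset_gap_ms) {
      cur <- cur + 1L
      in_trial <- TRUE
    } else if (gap > ricochet_gap_ms) {
      in_trial <- FALSE          # ricochet onset
    }                            # else: inherit previous reading's status
    if (in_trial) trial[i] <- cur
  }
  out <- as_tibble(readings)
  out$trial <- trial
  attr(out, "n_discarded") <- sum(is.na(trial))
  out
}

#' Per-trial features: mean of the first few samples
#'
#' Waiting for a whole trial would delay playback, so the pipeline (and the
#' calibration analysis mirroring it) uses only up to the first
#' `max_samples` readings of each trial and averages them.
#'
#' @param segmented Output of [segment_trials()] (discarded readings are
#'   ignored), or any data frame with `t_ms`, `sum`, `trial`.
#' @param max_samples Retention cap per trial. Default 10.
#' @return A tibble with one row per trial: `trial`, `onset_ms`,
#'   `n_samples` (full trial length), `n_used` (samples entering the mean,
#'   `<= max_samples`), `feature` (the mean reading).
#' @export
trial_features <- function(segmented, max_samples = 10L) {
  if (!all(c("t_ms", "sum", "trial") %in% names(segmented))) {
    abort("segmented readings need columns t_ms, sum, trial")
  }
  segmented %>%
    filter(!is.na(.data$trial)) %>%
    arrange(.data$t_ms) %>%
    group_by(trial = .data$trial) %>%
    summarise(
      onset_ms = first(.data$t_ms),
      n_samples = n(),
      n_used = min(n(), max_samples),
      feature = mean(head(.data$sum, max_samples)),
      .groups = "drop"
    )
}

#' Fit the drop-height calibration line
#'
#' Ordinary least squares of the per-trial mean reading on fall height:
#' `r = a + b * d + e`, with `r` in counts and `d` in centimetres. Impact
#' force is approximately linear in fall height and piezo current is linear
#' in strain force, so the summed reading is modelled as linear in height.
#'
#' @param trial_data A data frame with one row per trial carrying `feature`
#'   (mean reading, counts) and `height_cm`. At least 3 trials spanning more
#'   than one distinct height are required.
#' @return An object of class `calibration_fit` wrapping the `lm` fit, with
#'   [broom::tidy()] and [broom::glance()] methods. Key quantities:
#'   `intercept`, `slope`, `adj_r2`, `f_stat` (on 1 and n-2 df), `t_slope`,
#'   `t_intercept`, `residual_sd`, `n`.
#' @examples
#' s <- gen_drop_session(seed = 1)
#' seg <- segment_trials(s$readings)
#' fit <- trial_features(seg) |>
#'   dplyr::left_join(s$truth, by = "trial") |>
#'   fit_calibration()
#' broom::glance(fit)
#' @export
fit_calibration <- function(trial_data) {
  if (!all(c("feature", "height_cm") %in% names(trial_data))) {
    abort("trial_data needs columns feature and height_cm")
  }
  if (nrow(trial_data) < 3L) abort("need at least 3 trials")
  if (length(unique(trial_data$height_cm)) < 2L) {
    abort("singular design: all drop heights identical")
  }
  fit <- lm(feature ~ height_cm, data = trial_data)
  sm <- summary(fit)
  structure(list(
    lm = fit,
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    adj_r2 = sm$adj.r.squared,
    f_stat = unname(sm$fstatistic["value"]),
    t_intercept = sm$coefficients[1, "t value"],
    t_slope = sm$coefficients[2, "t value"],
    residual_sd = sm$sigma,
    n = nrow(trial_data)
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit>  r =", format(x$intercept, digits = 6), "+",
      format(x$slope, digits = 4), "* d  (counts per cm)\n")
  cat("  n =", x$n, " adj R^2 =", format(x$adj_r2, digits = 3),
      " F(1,", x$n - 2, ") =", format(x$f_stat, digits = 4), "\n")
  invisible(x)
}

#' @exportS3Method broom::tidy
tidy.calibration_fit <- function(x, ...) broom::tidy(x$lm, ...)

#' @exportS3Method broom::glance
glance.calibration_fit <- function(x, ...) {
  tibble(n = x$n, intercept = x$intercept, slope = x$slope,
         adj_r2 = x$adj_r2, f_stat = x$f_stat,
         t_intercept = x$t_intercept, t_slope = x$t_slope,
         residual_sd = x$residual_sd)
}

#' Onset-aligned strain-type profiles with per-bin Welch tests
#'
#' Repetitions of two manipulation types (superficial *hit* vs
#' surface-displacing *thrust*) are aligned so each repetition's first
#' reading sits at t = 0, then binned into `bin_ms` windows. Within each
#' bin, each repetition contributes its mean reading; across repetitions the
#' function reports the mean with a Student-t 95% confidence interval per
#' condition, plus a Welch two-sample t statistic (unequal variances,
#' Satterthwaite degrees of freedom; sign convention hit - thrust) wherever
#' both conditions have at least two repetitions in the bin.
#'
#' The recommended second-stage detector threshold is the lower confidence
#' bound of the thrust condition in the bin containing the confirmation
#' delay (5 ms by default) — the value the deployed detector rounds to 1765.
#'
#' @param hit_reps,thrust_reps Long data frames with columns `rep`, `t_ms`,
#'   `sum`; at least 2 repetitions per condition.
#' @param bin_ms Bin width in milliseconds. Default 5 (the maximum time
#'   resolution of the transmission settings).
#' @param stage2_delay_ms Delay whose bin supplies the threshold
#'   recommendation. Default 5.
#' @param conf_level Confidence level for the per-bin intervals.
#' @return A list of class `strain_profile` with `$profile` (tibble:
#'   `bin_start_ms`, `cond`, `mean`, `ci_lo`, `ci_hi`, `n`), `$tests`
#'   (tibble: `bin_start_ms`, `t`, `df`, `p`, `n_hit`, `n_thrust`) and
#'   `$stage2_recommendation` (counts).
#' @export
profile_strain_types <- function(hit_reps, thrust_reps, bin_ms = 5L,
                                 stage2_delay_ms = 5L, conf_level = 0.95) {
  align_bin <- function(reps, cond) {
    if (!all(c("rep", "t_ms", "sum") %in% names(reps))) {
      abort("repetitions need columns rep, t_ms, sum")
    }
    counts <- dplyr::count(reps, .data$rep)
    if (nrow(counts) < 2L) abort("need at least 2 repetitions per condition")
    if (any(counts$n == 0L)) abort("repetition with no samples")
    reps %>%
      group_by(rep = .data$rep) %>%
      mutate(rel_ms = .data$t_ms - min(.data$t_ms)) %>%
      ungroup() %>%
      mutate(bin_start_ms = (.data$rel_ms %/% bin_ms) * bin_ms, cond = cond) %>%
      group_by(.data$cond, .data$bin_start_ms, .data$rep) %>%
      summarise(rep_mean = mean(.data$sum), .groups = "drop")
  }
  per_rep <- bind_rows(align_bin(hit_reps, "hit"), align_bin(thrust_reps, "thrust"))
  alpha <- 1 - conf_level
  profile <- per_rep %>%
    group_by(.data$cond, .data$bin_start_ms) %>%
    summarise(
      mean = mean(.data$rep_mean),
      ci_lo = if (n() > 1L && sd(.data$rep_mean) > 0)
        mean(.data$rep_mean) - qt(1 - alpha / 2, n() - 1L) * sd(.data$rep_mean) / sqrt(n())
      else mean(.data$rep_mean),
      ci_hi = if (n() > 1L && sd(.data$rep_mean) > 0)
        mean(.data$rep_mean) + qt(1 - alpha / 2, n() - 1L) * sd(.data$rep_mean) / sqrt(n())
      else mean(.data$rep_mean),
      n = n(),
      .groups = "drop"
    ) %>%
    arrange(.data$bin_start_ms, .data$cond)

  bins <- sort(unique(per_rep$bin_start_ms))
  tests <- purrr::map_dfr(bins, function(b) {
    h <- per_rep$rep_mean[per_rep$cond == "hit" & per_rep$bin_start_ms == b]
    th <- per_rep$rep_mean[per_rep$cond == "thrust" & per_rep$bin_start_ms == b]
    if (length(h) < 2L || length(th) < 2L) return(NULL)
    if (sd(h) == 0 && sd(th) == 0) {
      # degenerate: identical repetitions carry no variance; report t = 0
      return(tibble(bin_start_ms = b, t = 0, df = NA_real_, p = NA_real_,
                    n_hit = length(h), n_thrust = length(th)))
    }
    tt <- stats::t.test(h, th, var.equal = FALSE)
    tibble(bin_start_ms = b, t = unname(tt$statistic), df = unname(tt$parameter),
           p = tt$p.value, n_hit = length(h), n_thrust = length(th))
  })

  delay_bin <- (stage2_delay_ms %/% bin_ms) * bin_ms
  rec <- profile$ci_lo[profile$cond == "thrust" & profile$bin_start_ms == delay_bin]
  structure(list(
    profile = profile,
    tests = tests,
    stage2_recommendation = if (length(rec) == 1L) rec else NA_real_,
    bin_ms = bin_ms
  ), class = "strain_profile")
}

#' @export
print.strain_profile <- function(x, ...) {
  cat("<strain_profile>", length(unique(x$profile$bin_start_ms)), "bins of",
      x$bin_ms, "ms;", nrow(x$tests), "Welch-testable bins\n")
  cat("  stage-2 threshold recommendation:",
      format(x$stage2_recommendation, digits = 6), "counts\n")
  invisible(x)
}
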