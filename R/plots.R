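# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_hline geom_abline labs theme_minimal facet_wrap
NULL

#' Plot an onset-aligned strain-type profile
#'
#' Mean summed reading per 5 ms bin with its confidence ribbon, one colour
#' per condition; the horizontal line marks the stage-2 detector threshold
#' recommended from the thrust profile.
#'
#' @param object A `strain_profile` from [profile_strain_types()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.strain_profile <- function(object, ...) {
  ggplot(object$profile, aes(x = .data$bin_start_ms, y = .data$mean,
                             colour = .data$cond, fill = .data$cond)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                alpha = 0.25, colour = NA) +
    geom_line() +
    geom_hline(yintercept = object$stage2_recommendation, linetype = "dashed") +
    labs(x = "time since onset (ms)", y = "summed reading (counts)",
         colour = "condition", fill = "condition") +
    theme_minimal()
}

#' Plot a drop-height calibration fit
#'
#' Per-trial mean readings against fall height with the fitted line.
#'
#' @param object A `calibration_fit` from [fit_calibration()].
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.calibration_fit <- function(object, ...) {
  ggplot(object$lm$model, aes(x = .data$height_cm, y = .data$feature)) +
    geom_point() +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "steelblue") +
    labs(x = "fall height (cm)", y = "mean reading (counts)") +
    theme_minimal()
}

#' Plot a motion stream with its jerk trace
#'
#' Two panels in the style of the device's live display: raw per-axis
#' accelerations, and the computed jerk against the activation threshold.
#'
#' @param frames A motion stream (`t_ms`, `ax`, `ay`, `az`).
#' @param cfg A [motion_config()] supplying the threshold line.
#' @return A ggplot.
#' @export
plot_motion_stream <- function(frames, cfg = motion_config()) {
  s <- add_jerk(frames)
  long <- bind_rows(
    tidyr::pivot_longer(s[c("t_ms", "ax", "ay", "az")], -"t_ms",
                        names_to = "series", values_to = "value") %>%
      mutate(panel = "acceleration (counts)"),
    tibble(t_ms = s$t_ms, series = "jerk", value = s$jerk,
           panel = "jerk (counts)")
  )
  thr <- tibble(panel = "jerk (counts)", y = cfg$activation_threshold)
  ggplot(long, aes(x = .data$t_ms, y = .data$value, colour = .data$series)) +
    geom_line() +
    geom_hline(data = thr, aes(yintercept = .data$y), linetype = "dashed",
               colour = "darkgreen") +
    facet_wrap(~panel, ncol = 1, scales = "free_y") +
    labs(x = "time (ms)", y = NULL, colour = NULL) +
    theme_minimal()
}
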