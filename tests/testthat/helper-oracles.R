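# Brute-force oracles, written directly from the stated rules and kept
# independent of the package's scanning implementations.

# Two-stage thrust rule, re-applied sample by sample with vectorised lookup.
oracle_thrusts <- function(t, v, cfg) {
  out <- NULL
  last_trigger <- -Inf
  for (i in seq_along(t)) {
    if (v[i] <= cfg$stage1_threshold) next
    if (t[i] - last_trigger < cfg$refractory_ms) next
    later <- which(t >= t[i] + cfg$stage2_delay_ms)
    if (length(later) == 0L) next
    j <- min(later)
    if (t[j] > t[i] + 2 * cfg$stage2_delay_ms) next
    if (v[j] > cfg$stage2_threshold) {
      out <- rbind(out, c(t_ms = t[i] + cfg$stage2_delay_ms, magnitude = v[j]))
      last_trigger <- t[i]
    }
  }
  if (is.null(out)) data.frame(t_ms = integer(), magnitude = numeric())
  else as.data.frame(out)
}

# Continuously reset debounce rule on a precomputed jerk series.
oracle_shakes <- function(t, jerk, cfg) {
  out <- NULL
  last_act <- -Inf
  for (i in seq_along(t)[-1]) {
    if (jerk[i] > cfg$activation_threshold) {
      if (t[i] - last_act >= cfg$refractory_ms) {
        out <- rbind(out, c(t_ms = t[i], magnitude = jerk[i]))
      }
      last_act <- t[i]
    }
  }
  if (is.null(out)) data.frame(t_ms = integer(), magnitude = numeric())
  else as.data.frame(out)
}

# Textbook Welch statistic and Satterthwaite degrees of freedom.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  list(
    t = (mean(x) - mean(y)) / sqrt(vx + vy),
    df = (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  )
}

# Random pre-summed strain stream exercising all detector branches.
random_sum_stream <- function(seed, n = 400) {
  set.seed(seed)
  tibble::tibble(
    t_ms = cumsum(sample(1:8, n, replace = TRUE)),
    sum = sample(0:4092, n, replace = TRUE)
  )
}

# Random motion stream with occasional large jumps.
random_motion_stream <- function(seed, n = 300) {
  set.seed(seed)
  jump <- sample(c(0, 1), n, replace = TRUE, prob = c(0.85, 0.15))
  a <- function() pmin(pmax(round(128 + cumsum(rnorm(n, 0, 2)) + jump * rnorm(n, 0, 40)), 0), 255)
  tibble::tibble(t_ms = seq(0L, by = 10L, length.out = n),
                 ax = a(), ay = a(), az = a())
}
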