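test_that("segmentation separates trials, keeps clusters and drops ricochet", {
  # single burst of 5 readings 100 ms apart
  b <- tibble::tibble(t_ms = seq(0L, 400L, 100L), sum = 1200)
  seg <- segment_trials(b)
  expect_equal(seg$trial, rep(1L, 5))
  expect_equal(attr(seg, "n_discarded"), 0L)

  # burst plus a lone echo 700 ms later
  be <- tibble::tibble(t_ms = c(seq(0L, 400L, 100L), 1100L), sum = 1200)
  seg2 <- segment_trials(be)
  expect_equal(sum(!is.na(seg2$trial)), 5L)
  expect_equal(attr(seg2, "n_discarded"), 1L)
  expect_equal(max(seg2$trial, na.rm = TRUE), 1L)

  # empty input
  seg0 <- segment_trials(tibble::tibble(t_ms = integer(), sum = numeric()))
  expect_equal(nrow(seg0), 0L)
  expect_equal(attr(seg0, "n_discarded"), 0L)
})

test_that("a seeded protocol session yields 45 trials with echoes discarded", {
  s <- gen_drop_session(seed = 42)
  seg <- segment_trials(s$readings)
  expect_equal(max(seg$trial, na.rm = TRUE), 45L)
  expect_equal(attr(seg, "n_discarded"), s$n_echoes)
  expect_gt(s$n_echoes, 0L)
})

test_that("every reading lands in exactly one trial or the discard pile", {
  for (seed in c(1, 7, 23)) {
    s <- gen_drop_session(seed = seed)
    seg <- segment_trials(s$readings)
    expect_equal(nrow(seg), nrow(s$readings))
    expect_equal(sum(!is.na(seg$trial)) + attr(seg, "n_discarded"), nrow(seg))
    # widening the ricochet window never loses readings
    wide <- segment_trials(s$readings, ricochet_gap_ms = 1000L)
    expect_gte(sum(!is.na(wide$trial)), sum(!is.na(seg$trial)))
  }
})

test_that("trial features average at most the first ten samples", {
  seg <- tibble::tibble(t_ms = seq(0L, by = 40L, length.out = 12),
                        sum = 1500, trial = 1L)
  f <- trial_features(seg)
  expect_equal(f$feature, 1500)
  expect_equal(f$n_used, 10L)
  expect_equal(f$n_samples, 12L)

  one <- trial_features(tibble::tibble(t_ms = 0L, sum = 1200, trial = 1L))
  expect_equal(one$feature, 1200)

  three <- trial_features(tibble::tibble(t_ms = c(0L, 40L, 80L),
                                         sum = c(1000, 2000, 3000), trial = 1L))
  expect_equal(three$feature, 2000)
})

test_that("the calibration fit recovers a noiseless line to machine precision", {
  s <- gen_drop_session(residual_sd = 0, ricochet_prob = 0, seed = 3)
  seg <- segment_trials(s$readings)
  fit <- suppressWarnings(
    fit_calibration(dplyr::left_join(trial_features(seg), s$truth, by = "trial"))
  )
  expect_equal(fit$slope, 3.00, tolerance = 1e-10)
  expect_equal(fit$intercept, 1208.29, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)

  # two-point line
  two <- tibble::tibble(feature = c(10, 17), height_cm = c(0, 1))
  f2 <- suppressWarnings(fit_calibration(rbind(two, c(13.5, 0.5))))
  expect_equal(f2$intercept, 10, tolerance = 1e-9)
  expect_equal(f2$slope, 7, tolerance = 1e-9)

  sing <- tibble::tibble(feature = c(1, 2, 3), height_cm = 50)
  expect_error(fit_calibration(sing), "singular")
})

test_that("noisy-session parameter recovery is unbiased", {
  est <- vapply(1:30, function(seed) {
    s <- gen_drop_session(seed = seed, ricochet_prob = 0)
    fit <- fit_calibration(dplyr::left_join(trial_features(segment_trials(s$readings)),
                                            s$truth, by = "trial"))
    c(fit$slope, fit$intercept)
  }, numeric(2))
  expect_equal(mean(est[1, ]), 3.00, tolerance = 0.1)
  expect_equal(mean(est[2, ]), 1208.29, tolerance = 0.02)
  # bias vanishes with the noise
  est0 <- vapply(1:5, function(seed) {
    s <- gen_drop_session(seed = seed, residual_sd = 1, ricochet_prob = 0)
    suppressWarnings(fit_calibration(dplyr::left_join(
      trial_features(segment_trials(s$readings)), s$truth, by = "trial")))$slope
  }, numeric(1))
  expect_equal(mean(est0), 3.00, tolerance = 0.01)
})

test_that("identical repetitions give degenerate profiles with zero t", {
  rep1 <- tibble::tibble(rep = 1L, t_ms = seq(0L, 20L, 1L), sum = 1500)
  reps <- dplyr::bind_rows(rep1, dplyr::mutate(rep1, rep = 2L))
  prof <- profile_strain_types(reps, reps)
  expect_true(all(prof$tests$t == 0))
  expect_true(all(prof$profile$ci_hi - prof$profile$ci_lo == 0))
})

test_that("hit and thrust profiles separate at the 5 ms bin", {
  mk <- function(kind, n) {
    purrr::map_dfr(seq_len(n), function(i) {
      p <- sum_frames(gen_strain_pulse(kind, seed = 1000 + i))
      tibble::tibble(rep = i, t_ms = p$t_ms, sum = p$sum)
    })
  }
  prof <- profile_strain_types(mk("hit", 59), mk("thrust", 59))
  t5 <- prof$tests$t[prof$tests$bin_start_ms == 5]
  expect_lt(t5, -2)            # sign convention hit - thrust; thrust higher at 5 ms
  expect_gt(abs(t5), 2)
  # CI brackets the mean in every bin
  expect_true(all(prof$profile$ci_lo <= prof$profile$mean + 1e-12))
  expect_true(all(prof$profile$ci_hi >= prof$profile$mean - 1e-12))
  # the stage-2 recommendation comes from the thrust lower bound at the delay bin
  thr5 <- prof$profile[prof$profile$cond == "thrust" & prof$profile$bin_start_ms == 5, ]
  expect_equal(prof$stage2_recommendation, thr5$ci_lo)
  expect_lt(prof$stage2_recommendation, thr5$mean)
})

test_that("profile CI width shrinks like one over the square root of reps", {
  mk <- function(n, sd_) {
    set.seed(99)
    purrr::map_dfr(seq_len(n), function(i)
      tibble::tibble(rep = i, t_ms = 0:9, sum = 1500 + rnorm(10, 0, sd_)))
  }
  w <- function(reps) {
    prof <- profile_strain_types(reps, mk(10, 50))
    pr <- prof$profile[prof$profile$cond == "hit" & prof$profile$bin_start_ms == 0, ]
    pr$ci_hi - pr$ci_lo
  }
  set.seed(1)
  w16 <- w(mk(16, 50)); w64 <- w(mk(64, 50))
  expect_equal(w64 / w16, 0.5, tolerance = 0.35)
})

test_that("per-bin Welch statistics match the textbook formulas", {
  set.seed(4)
  for (k in 1:10) {
    x <- rnorm(sample(4:12, 1), 10, 2)
    y <- rnorm(sample(4:12, 1), 12, 5)
    tt <- t.test(x, y, var.equal = FALSE)
    or <- oracle_welch(x, y)
    expect_equal(unname(tt$statistic), or$t, tolerance = 1e-12)
    expect_equal(unname(tt$parameter), or$df, tolerance = 1e-12)
  }
  # equal variance, equal n: Satterthwaite df collapses to 2n - 2
  x <- c(1, 2, 3, 4); y <- c(5, 6, 7, 8)
  expect_equal(oracle_welch(x, y)$df, 2 * 4 - 2, tolerance = 1e-12)

  # the profile's Welch column agrees with the oracle on generated reps
  mk <- function(mu, n, seed) {
    set.seed(seed)
    purrr::map_dfr(seq_len(n), function(i)
      tibble::tibble(rep = i, t_ms = 0:4, sum = mu + rnorm(5, 0, 30)))
  }
  h <- mk(1300, 8, 21); th <- mk(2000, 9, 22)
  prof <- profile_strain_types(h, th)
  hm <- dplyr::summarise(dplyr::group_by(h, rep), m = mean(sum))$m
  tm <- dplyr::summarise(dplyr::group_by(th, rep), m = mean(sum))$m
  or <- oracle_welch(hm, tm)
  row <- prof$tests[prof$tests$bin_start_ms == 0, ]
  expect_equal(row$t, or$t, tolerance = 1e-10)
  expect_equal(row$df, or$df, tolerance = 1e-10)
})

test_that("fit objects expose broom-style tidiers", {
  s <- gen_drop_session(seed = 5)
  fit <- fit_calibration(dplyr::left_join(trial_features(segment_trials(s$readings)),
                                          s$truth, by = "trial"))
  td <- broom::tidy(fit)
  expect_equal(nrow(td), 2L)
  gl <- broom::glance(fit)
  expect_equal(gl$n, 45L)
  expect_equal(gl$slope, fit$slope)
  expect_equal(unname(summary(fit$lm)$fstatistic["dendf"]), 43)
})
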