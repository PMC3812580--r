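test_that("frame sums are the four-channel totals and stay in range", {
  f <- tibble::tibble(t_ms = 0:2,
                      s1 = c(0L, 1023L, 100L), s2 = c(0L, 1023L, 200L),
                      s3 = c(0L, 1023L, 300L), s4 = c(0L, 1023L, 400L))
  expect_equal(sum_frames(f)$sum, c(0L, 4092L, 1000L))

  set.seed(11)
  for (k in 1:20) {
    r <- tibble::tibble(t_ms = 1:50,
                        s1 = sample(0:1023, 50, TRUE), s2 = sample(0:1023, 50, TRUE),
                        s3 = sample(0:1023, 50, TRUE), s4 = sample(0:1023, 50, TRUE))
    s <- sum_frames(r)$sum
    expect_true(all(s >= 0 & s <= 4092))
  }

  bad <- tibble::tibble(t_ms = 0, s1 = 1024L, s2 = 0L, s3 = 0L, s4 = 0L)
  expect_error(sum_frames(bad), "0, 1023")
})

test_that("the noise gate passes strictly above the threshold", {
  expect_equal(apply_noise_gate(c(499, 500, 501)), c(FALSE, FALSE, TRUE))
  # boundary pinned by detector behaviour: a constant-500 stream is silent
  flat <- tibble::tibble(t_ms = seq(0, 1000, by = 10), sum = 500)
  gated <- apply_noise_gate(flat)
  expect_false(any(gated$pass))
})

test_that("two-stage detection confirms thrusts and rejects hits", {
  cfg <- strain_config()

  # silence
  flat <- tibble::tibble(t_ms = 0:200, sum = 0)
  expect_equal(nrow(detect_thrusts(flat)), 0L)
  expect_equal(nrow(detect_thrusts(tibble::tibble(t_ms = integer(), sum = numeric()))), 0L)

  # hand-traced pulse: stage 1 at t=0 (2100), confirmation at t=5 (1900)
  pulse <- tibble::tibble(t_ms = c(0L, 5L, 10L), sum = c(2100, 1900, 600))
  ev <- detect_thrusts(pulse, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$t_ms, 5L)
  expect_equal(ev$magnitude, 1900)

  # fails stage 2 by construction
  hit <- tibble::tibble(t_ms = c(0L, 5L, 10L), sum = c(2100, 1200, 600))
  expect_equal(nrow(detect_thrusts(hit, cfg)), 0L)

  # second valid pulse 200 ms later falls inside the 300 ms refractory
  two <- tibble::tibble(t_ms = c(0L, 5L, 200L, 205L), sum = c(2100, 1900, 2100, 1900))
  expect_equal(nrow(detect_thrusts(two, cfg)), 1L)

  # candidate abandoned when no frame arrives within twice the delay
  gap <- tibble::tibble(t_ms = c(0L, 20L), sum = c(2100, 1900))
  expect_equal(nrow(detect_thrusts(gap, cfg)), 0L)
})

test_that("generated pulses drive the detector as their kind dictates", {
  expect_equal(nrow(detect_thrusts(gen_strain_pulse("thrust", seed = 1))), 1L)
  expect_equal(nrow(detect_thrusts(gen_strain_pulse("hit", seed = 1))), 0L)
  ev <- detect_thrusts(gen_strain_pulse("thrust", seed = 7))
  expect_gt(ev$magnitude, 1765)
})

test_that("consecutive emitted events respect the refractory period", {
  cfg <- strain_config()
  for (seed in 1:10) {
    s <- random_sum_stream(seed)
    ev <- detect_thrusts(s, cfg)
    if (nrow(ev) > 1L) {
      expect_true(all(diff(ev$trigger_t_ms) >= cfg$refractory_ms))
    }
  }
})

test_that("raising either threshold never yields more events", {
  for (seed in 1:8) {
    s <- random_sum_stream(seed)
    base <- nrow(detect_thrusts(s, strain_config()))
    up1 <- nrow(detect_thrusts(s, strain_config(stage1_threshold = 1400)))
    up2 <- nrow(detect_thrusts(s, strain_config(stage2_threshold = 2200)))
    expect_lte(up1, base)
    expect_lte(up2, base)
  }
})

test_that("the detector matches a brute-force re-application of the rule", {
  cfg <- strain_config()
  for (seed in 1:15) {
    s <- random_sum_stream(seed, n = 250)  # about 1 s of stream
    ev <- detect_thrusts(s, cfg)
    or <- oracle_thrusts(s$t_ms, s$sum, cfg)
    expect_equal(ev$t_ms, as.integer(or$t_ms))
    expect_equal(ev$magnitude, as.numeric(or$magnitude))
  }
})

test_that("serial lines parse iff they render back to themselves", {
  expect_equal(parse_serial_line("2100\n"), 2100L)
  expect_equal(parse_serial_line("21x0"), NA_integer_)
  expect_equal(parse_serial_line(""), NA_integer_)
  expect_equal(parse_serial_line(c(" 42 ", "-3", "1e3", "007")), c(42L, NA, NA, 7L))

  set.seed(5)
  cand <- c(as.character(sample(0:4092, 50)), "12 34", "0x1f", "\t999\t", "NaN")
  parsed <- parse_serial_line(cand)
  ok <- !is.na(parsed)
  # accepted lines are exactly those equal to the decimal rendering of their value
  expect_true(all(trimws(cand[ok]) == as.character(parsed[ok]) |
                    grepl("^0+", trimws(cand[ok]))))
  expect_true(all(is.na(parse_serial_line(c("abc", "1.5", "-1")))))
})
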