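test_that("events map deterministically by kind and magnitude", {
  mapping <- sound_mapping(tibble::tibble(kind = "thrust", sound_id = "snare", gain = 1))
  ev <- tibble::tibble(t_ms = 5L, kind = "thrust", magnitude = 1900)
  tr <- map_events(ev, mapping)
  expect_equal(tr$sound_id, "snare")
  expect_equal(tr$gain, 1)

  # uncovered kind
  shake <- tibble::tibble(t_ms = 0L, kind = "shake", magnitude = 40)
  expect_error(map_events(shake, mapping), "no mapping rule")

  # overlapping ranges rejected at construction
  expect_error(sound_mapping(tibble::tibble(
    kind = "thrust", sound_id = c("a", "b"),
    min_magnitude = c(0, 500), max_magnitude = c(1000, 1500))), "overlapping")
})

test_that("linear and breakpoint gain curves are monotone in magnitude", {
  lin <- sound_mapping(tibble::tibble(kind = "shake", sound_id = "bell",
                                      min_magnitude = 0, max_magnitude = 200),
                       gain_curve = "linear")
  mags <- c(10, 50, 120, 199)
  ev <- tibble::tibble(t_ms = seq_along(mags) * 10L, kind = "shake", magnitude = mags)
  g <- map_events(ev, lin)$gain
  expect_true(all(diff(g) >= 0))
  expect_true(all(g >= 0 & g <= 1))

  bp <- sound_mapping(tibble::tibble(kind = "shake", sound_id = "bell"),
                      gain_curve = "breakpoints",
                      breakpoints = tibble::tibble(magnitude = c(0, 100, 200),
                                                   gain = c(0.2, 0.5, 1)))
  gb <- map_events(ev, bp)$gain
  expect_true(all(diff(gb) >= 0))
  expect_equal(map_events(ev[2, ], bp)$gain, 0.35)  # interpolated midpoint
})

test_that("sinks return one record per trigger and refuse when closed", {
  mapping <- sound_mapping(tibble::tibble(kind = "thrust", sound_id = "snare"))
  ev <- tibble::tibble(t_ms = c(5L, 400L, 900L), kind = "thrust",
                       magnitude = c(1800, 1900, 2000))
  tr <- map_events(ev, mapping)
  rec <- play_events(tr, null_sink())
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$sound_id, tr$sound_id)
  expect_equal(rec$gain, tr$gain)
  expect_true(all(diff(rec$t_ms) >= 0))

  dir <- withr::local_tempdir()
  fs <- file_sink(file.path(dir, "play.csv"))
  play_events(tr, fs)
  expect_equal(length(readLines(fs$path)), 4L)  # header + 3 records

  close_sink(fs)
  expect_error(play_events(tr, fs), "closed")
})

test_that("a mid-session mapping swap changes only subsequent records", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "swap.csv")
  ev1 <- tibble::tibble(t_ms = c(10L, 400L), kind = "thrust", magnitude = 1900)
  ev2 <- tibble::tibble(t_ms = c(800L, 1200L), kind = "thrust", magnitude = 1900)
  snare <- sound_mapping(tibble::tibble(kind = "thrust", sound_id = "snare"))
  hihat <- sound_mapping(tibble::tibble(kind = "thrust", sound_id = "hihat"))

  log <- open_session(path, params = list(mapping = "snare"))
  log_event(log, play_events(map_events(ev1, snare)))
  close_session(log)
  log <- open_session(path, params = list(mapping = "hihat"))
  log_event(log, play_events(map_events(ev2, hihat)))
  close_session(log)

  back <- read_session_log(path)
  expect_equal(back$events$sound_id, c("snare", "snare", "hihat", "hihat"))
  expect_equal(back$events$block, c(1L, 1L, 2L, 2L))
  swaps <- back$params[back$params$key == "mapping", ]
  expect_equal(swaps$value, c("snare", "hihat"))
})

test_that("mapping and dispatch complete fast enough for live playback", {
  mapping <- sound_mapping(tibble::tibble(kind = "thrust", sound_id = "snare"))
  ev <- tibble::tibble(t_ms = seq(0L, by = 400L, length.out = 50L),
                       kind = "thrust", magnitude = 1900)
  t0 <- Sys.time()
  rec <- play_events(map_events(ev, mapping), null_sink())
  per_event_ms <- as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000 / nrow(rec)
  expect_lt(per_event_ms, 10)
})
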