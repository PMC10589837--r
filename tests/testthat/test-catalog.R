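test_that("the hit-window schedule honours its anchors and interpolates linearly", {
  expect_equal(window_width_for_tempo(55), 1000)
  expect_equal(window_width_for_tempo(110), 100)
  # derived: linear between (60, 1000) and (100, 100): 80 bpm -> 550 ms
  expect_equal(window_width_for_tempo(80),
               1000 + (80 - 60) / (100 - 60) * (100 - 1000))
  expect_equal(window_width_for_tempo(80), 550)
  expect_error(window_width_for_tempo(0), "positive")
  expect_error(window_width_for_tempo(-10), "positive")
})

test_that("the window schedule is monotone non-increasing and bounded", {
  grid <- seq(30, 130, by = 0.25)
  w <- window_width_for_tempo(grid)
  expect_true(all(diff(w) <= 0))
  expect_true(all(w >= 100 & w <= 1000))
})

test_that("build_timeline expands patterns at the right millisecond grid", {
  # one tap per beat at 60 bpm: 1000 ms apart starting at 0
  spec <- session_spec(1L, "test", 60, make_pulse(4, "left"), 1L)
  tl <- build_timeline(spec)
  expect_equal(tl$beats$onset_ms, c(0, 1000, 2000, 3000))
  expect_equal(tl$total_targets, 4L)
  expect_equal(tl$beats$hand, rep("left", 4))

  # paradiddle half-beat strokes at 100 bpm: IOI 300 ms, so every
  # half-window is clamped to at most 0.45 * 300 = 135 ms
  spec2 <- session_spec(8L, "fast", 100, make_paradiddle(1), 4L,
                        hands_mode = "both_reversed")
  tl2 <- build_timeline(spec2)
  expect_equal(diff(tl2$beats$onset_ms), rep(300, 31))
  expect_true(all(tl2$beats$half_window_ms <= 0.45 * 300))

  # clamping guarantee: windows pairwise disjoint
  lo <- tl2$beats$onset_ms - tl2$beats$half_window_ms
  hi <- tl2$beats$onset_ms + tl2$beats$half_window_ms
  expect_true(all(hi[-length(hi)] < lo[-1]))
})

test_that("the default catalog matches the published program shape", {
  cat22 <- default_catalog()
  expect_equal(length(training_sessions(cat22)), 22L)
  expect_equal(length(cat22$sessions), 23L)
  expect_equal(cat22$unlock_threshold, 0.70)

  tempos <- vapply(training_sessions(cat22), `[[`, 0, "tempo_bpm")
  expect_equal(max(tempos), 117)
  expect_lt(tempos[1], 60)              # session 1 under one beat/second
  expect_true(all(diff(tempos) >= 0))

  s1 <- catalog_session(cat22, 1)
  expect_false(s1$has_metronome)        # slow opener without metronome
  expect_equal(length(s1$pattern$beat_offsets), 4L)  # taps on all 4 beats

  expect_true(validate_catalog(cat22))
})

test_that("catalog invariants hold across all sessions", {
  cat22 <- default_catalog()
  tr <- training_sessions(cat22)
  timelines <- lapply(tr, build_timeline)

  targets <- vapply(timelines, `[[`, 0L, "total_targets")
  expect_true(all(diff(targets) >= 0))

  for (tl in timelines) {
    b <- tl$beats
    expect_true(all(diff(b$onset_ms) > 0))
    expect_true(all(b$half_window_ms >= 50 & b$half_window_ms <= 500))
    lo <- b$onset_ms - b$half_window_ms
    hi <- b$onset_ms + b$half_window_ms
    expect_true(all(hi[-nrow(b)] < lo[-1]))
  }

  modes <- vapply(tr, `[[`, "", "hands_mode")
  idx <- vapply(tr, `[[`, 0L, "index")
  expect_true(all(modes[idx <= 7] == "separate_then_together"))
  expect_true(all(modes[idx >= 8] == "both_reversed"))

  tracks <- vapply(tr, `[[`, 0L, "background_track_id")
  expect_true(all(tapply(tracks, (idx - 1) %/% 3,
                         function(v) length(unique(v))) == 1))
})

test_that("validate_catalog flags broken programs", {
  broken <- default_catalog()
  broken$sessions[[2]]$tempo_bpm <- 117   # session 1 now above session 2
  expect_error(validate_catalog(broken), "non-decreasing")
  short <- default_catalog()
  short$sessions <- short$sessions[-5]
  expect_error(validate_catalog(short), "1..22")
})

test_that("a catalog survives the JSON round trip", {
  cat22 <- default_catalog()
  path <- withr::local_tempfile(fileext = ".json")
  write_catalog_json(cat22, path)
  back <- read_catalog_json(path)
  expect_true(validate_catalog(back))
  expect_equal(length(back$sessions), 23L)
  expect_equal(back$unlock_threshold, cat22$unlock_threshold)
  for (k in seq_along(cat22$sessions)) {
    a <- cat22$sessions[[k]]; b <- back$sessions[[k]]
    expect_equal(b$tempo_bpm, a$tempo_bpm)
    expect_equal(b$pattern$hands, a$pattern$hands)
    expect_equal(b$pattern$beat_offsets, a$pattern$beat_offsets)
    expect_equal(b$n_cycles, a$n_cycles)
  }
})
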