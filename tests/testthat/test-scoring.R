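test_that("matching scores the canonical two-target instance correctly", {
  inst <- two_target_instance()
  m <- match_taps(inst$timeline, inst$taps)
  expect_equal(m$records$accuracy, c(1L, 0L))
  expect_equal(m$records$latency_ms, c(100, NA_real_))
  expect_equal(nrow(m$extras), 1L)
  expect_equal(m$extras$classification, "outside_all_windows")

  s <- summarize_session(m$records, m$extras, inst$timeline)
  expect_equal(s$mean_accuracy, 0.5)
  expect_equal(s$mean_latency_ms, 100)
})

test_that("degenerate tap streams score as expected", {
  tl <- build_timeline(session_spec(1L, "t", 60, make_pulse(4, "left"), 2L))
  # no taps: all misses, no extras, latency fields missing (never 0)
  m0 <- match_taps(tl, tap_events())
  expect_true(all(m0$records$accuracy == 0L))
  expect_equal(nrow(m0$extras), 0L)
  s0 <- summarize_session(m0$records, m0$extras, tl)
  expect_equal(s0$mean_accuracy, 0)
  expect_true(is.na(s0$mean_latency_ms))
  expect_true(is.na(s0$min_left_latency_ms))

  # taps exactly on every onset: perfect accuracy, zero latency
  mp <- match_taps(tl, tap_events(tl$beats$onset_ms, tl$beats$hand))
  expect_true(all(mp$records$accuracy == 1L))
  expect_true(all(mp$records$latency_ms == 0))
  sp <- summarize_session(mp$records, mp$extras, tl)
  expect_equal(sp$mean_accuracy, 1)
  expect_equal(sp$mean_latency_ms, 0)
  expect_equal(sp$min_left_latency_ms, 0)
})

test_that("extra taps are classified by where and on which drum they fall", {
  tl <- target_timeline(1L, c(1000, 2000), c("left", "right"), 300)
  taps <- tap_events(c(1010, 1100, 1950, 3000),
                     c("left", "left", "left", "right"))
  m <- match_taps(tl, taps)
  expect_equal(m$records$accuracy, c(1L, 0L))
  expect_equal(m$records$latency_ms[1], 10)   # nearer tap wins
  expect_setequal(m$extras$classification,
                  c("surplus_in_window", "wrong_drum_in_window",
                    "outside_all_windows"))
  # wrong-drum tap inside the right-hand target's window does not rescue it
  expect_equal(m$records$accuracy[2], 0L)
})

test_that("equidistant taps break ties toward the earlier tap", {
  tl <- target_timeline(1L, 1000, "left", 300)
  m <- match_taps(tl, tap_events(c(1100, 900), c("left", "left")))
  expect_equal(m$records$latency_ms, -100)
  expect_equal(m$extras$timestamp_ms, 1100)
  expect_equal(m$extras$classification, "surplus_in_window")
})

test_that("per-hand summaries restrict to that hand's targets", {
  tl <- target_timeline(1L, c(1000, 2000, 3000, 4000),
                        c("left", "right", "left", "right"), 400)
  taps <- tap_events(c(1050, 2100, 2950), c("left", "right", "left"))
  m <- match_taps(tl, taps)
  s <- summarize_session(m$records, m$extras, tl)
  expect_equal(s$mean_accuracy, 0.75)
  expect_equal(s$mean_left_accuracy, 1)
  expect_equal(s$mean_right_accuracy, 0.5)
  expect_equal(s$mean_left_latency_ms, mean(c(50, -50)))
  expect_equal(s$mean_right_latency_ms, 100)
  expect_equal(s$min_left_latency_ms, 50)
  expect_equal(s$min_right_latency_ms, 100)
  # hand accuracies weighted by target counts recover the overall accuracy
  n_left <- sum(tl$beats$hand == "left")
  n_right <- sum(tl$beats$hand == "right")
  expect_equal((n_left * s$mean_left_accuracy +
                  n_right * s$mean_right_accuracy) / (n_left + n_right),
               s$mean_accuracy)
  expect_error(summarize_session(m$records, m$extras,
                                 target_timeline(1L, numeric(0),
                                                 character(0), numeric(0))),
               "zero target")
})

test_that("score_session fills the difficulty metadata", {
  slow <- session_spec(1L, "slow", 55, make_pulse(4, "left"), 2L)
  res <- score_session(slow, tap_events())
  expect_equal(res$metadata$window_duration_ms, 1000)
  expect_equal(res$metadata$success_threshold_pct, 70)
  expect_equal(res$metadata$total_targets, 8L)

  fast <- session_spec(9L, "fast", 110, make_paradiddle(1), 2L,
                       hands_mode = "both_reversed")
  expect_equal(score_session(fast, tap_events())$metadata$window_duration_ms,
               100)
})

test_that("matching conserves taps and ignores input order", {
  set.seed(202)
  for (rep in 1:30) {
    tl <- random_timeline(sample(0:12, 1))
    span <- if (tl$total_targets > 0) max(tl$beats$onset_ms) + 800 else 2000
    taps <- random_taps(sample(0:15, 1), span)
    m <- match_taps(tl, taps)
    # conservation: every tap is matched or an extra, exactly once
    expect_equal(sum(m$records$accuracy) + nrow(m$extras), nrow(taps))
    # accuracy-1 records stay inside their window
    hit <- m$records$accuracy == 1L
    expect_true(all(abs(m$records$latency_ms[hit]) <=
                      m$records$half_window_ms[hit]))
    # permutation invariance
    perm <- sample(nrow(taps))
    m2 <- match_taps(tl, tap_events(taps$timestamp_ms[perm],
                                    taps$drum[perm]))
    expect_equal(m2$records, m$records)
    expect_equal(m2$extras, m$extras)
  }
})

test_that("adding a tap never decreases the number of accurate records", {
  set.seed(303)
  for (rep in 1:25) {
    tl <- random_timeline(sample(1:8, 1))
    span <- max(tl$beats$onset_ms) + 800
    taps <- random_taps(sample(0:8, 1), span)
    before <- sum(match_taps(tl, taps)$records$accuracy)
    extra <- random_taps(1, span)
    taps2 <- tap_events(c(taps$timestamp_ms, extra$timestamp_ms),
                        c(taps$drum, extra$drum))
    after <- sum(match_taps(tl, taps2)$records$accuracy)
    expect_gte(after, before)
  }
})

test_that("greedy matching agrees with the exhaustive-search oracle", {
  set.seed(404)
  for (rep in 1:100) {
    tl <- random_timeline(sample(0:6, 1), min_gap = 150, max_gap = 700)
    span <- if (tl$total_targets > 0) max(tl$beats$onset_ms) + 500 else 1500
    taps <- random_taps(sample(0:6, 1), span)
    got <- match_taps(tl, taps)
    want <- oracle_match(tl, taps)
    expect_equal(got$records$accuracy, want$accuracy)
    expect_equal(abs(got$records$latency_ms), abs(want$latency))
  }
})

test_that("tap logs round trip through CSV", {
  taps <- tap_events(c(12.5, 340, 1001.25), c("left", "right", "left"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tap_log(taps, path)
  back <- read_tap_log(path)
  expect_equal(back$timestamp_ms, taps$timestamp_ms)
  expect_equal(back$drum, taps$drum)
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_tap_log(bad), "tap log")
})
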