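test_that("a noiseless tapper scores perfectly and a total misser scores zero", {
  spec <- session_spec(4L, "t", 70, make_paradiddle(1), 5L)
  tl <- build_timeline(spec)
  perfect <- simulate_taps(tl, tapper_profile(seed = 11))
  res <- score_session(spec, perfect)
  expect_equal(res$summary$mean_accuracy, 1.0)
  expect_equal(res$summary$mean_latency_ms, 0)

  none <- simulate_taps(tl, tapper_profile(miss_prob = 1, seed = 11))
  expect_equal(nrow(none), 0L)
  expect_equal(score_session(spec, none)$summary$mean_accuracy, 0)
})

test_that("simulation is reproducible from the profile seed", {
  tl <- build_timeline(session_spec(5L, "t", 80, make_paradiddle(1), 6L))
  p <- tapper_profile(30, 25, 0.1, 0.5, 0.05, seed = 99)
  a <- simulate_taps(tl, p)
  b <- simulate_taps(tl, p)
  expect_identical(a, b)
})

test_that("profiles reject invalid parameters and round trip as JSON", {
  expect_error(tapper_profile(miss_prob = 1.2), "\\[0, 1\\]")
  expect_error(tapper_profile(jitter_sd = -1))
  p <- tapper_profile(-20, 35, 0.15, 0.3, 0.02, seed = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_tapper_profile(p, path)
  expect_equal(read_tapper_profile(path), p)
})

test_that("simulated accuracy tracks the truncated-normal closed form", {
  # single-hand timeline so a wrong-drum tap can never be rescued by a
  # neighbouring opposite-hand target
  tl <- target_timeline(1L, seq(0, by = 1000, length.out = 200),
                        rep("left", 200), 250)
  p <- tapper_profile(40, 150, 0.2, 0, 0.1, seed = 21)
  accs <- vapply(1:40, function(s) {
    taps <- simulate_taps(tl, tapper_profile(40, 150, 0.2, 0, 0.1,
                                             seed = 1000 + s))
    score_timeline(tl, taps, tempo_bpm = 60)$summary$mean_accuracy
  }, numeric(1))
  expected <- expected_accuracy(p, 250)
  n_trials <- 40 * 200
  mc_se <- sqrt(expected * (1 - expected) / n_trials)
  expect_lt(abs(mean(accs) - expected), 4 * mc_se)
})

test_that("accurate-tap latencies follow a truncated normal (KS check)", {
  mu <- 20; sigma <- 80; hw <- 250
  tl <- target_timeline(1L, seq(1000, by = 1000, length.out = 10000),
                        rep("left", 10000), hw)
  taps <- simulate_taps(tl, tapper_profile(mu, sigma, 0, 0, 0, seed = 31))
  m <- match_taps(tl, taps)
  lat <- m$records$latency_ms[m$records$accuracy == 1L]
  denom <- stats::pnorm(hw, mu, sigma) - stats::pnorm(-hw, mu, sigma)
  ptrunc <- function(q) {
    pmin(1, pmax(0, (stats::pnorm(q, mu, sigma) -
                       stats::pnorm(-hw, mu, sigma)) / denom))
  }
  ks <- suppressWarnings(stats::ks.test(lat, ptrunc))
  expect_gt(ks$p.value, 0.01)
})

test_that("a compliant virtual participant unlocks the whole program", {
  cat22 <- default_catalog()
  sim <- simulate_program(cat22, tapper_profile(seed = 41), 5L, 8L)
  expect_setequal(sim$state$unlocked, 0:22)
  expect_equal(nrow(sim$engagement), 40L)
  expect_equal(adherence_summary(sim$engagement)$adherence_fraction, 1.0)
  # deterministic per seed
  sim2 <- simulate_program(cat22, tapper_profile(seed = 41), 5L, 8L)
  expect_identical(sim$engagement, sim2$engagement)
  expect_identical(sim$state$unlocked, sim2$state$unlocked)
})

test_that("a tapper who always misses never unlocks session 4", {
  cat22 <- default_catalog()
  sim <- simulate_program(cat22, tapper_profile(miss_prob = 1, seed = 51),
                          5L, 2L)
  expect_setequal(sim$state$unlocked, 0:3)
  expect_true(all(vapply(sim$results, function(r) r$summary$mean_accuracy,
                         numeric(1)) == 0))
})
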