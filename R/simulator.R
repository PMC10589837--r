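#' Virtual tapper profile
#'
#' Parameters of the simulated participant, following the standard
#' sensorimotor-synchronization noise model: each target is hit with
#' probability `1 - miss_prob`, at the target onset plus a Gaussian
#' asynchrony `N(mean_asynchrony, jitter_sd)`, on the wrong drum with
#' probability `wrong_hand_prob`; unrelated extra taps arrive as a
#' homogeneous Poisson stream at `extra_rate` events per second over the
#' session span.
#'
#' @param mean_asynchrony signed mean tap-minus-onset asynchrony in ms
#'   (negative values model the anticipatory tendency typical of paced
#'   tapping).
#' @param jitter_sd timing jitter SD in ms, >= 0.
#' @param miss_prob probability of skipping a target, in [0, 1].
#' @param extra_rate extra-tap rate in events/s, >= 0.
#' @param wrong_hand_prob probability a produced tap lands on the wrong
#'   drum, in [0, 1].
#' @param seed integer RNG seed; the whole simulation is reproducible
#'   from it.
#' @return An object of class `tapper_profile`.
#' @export
tapper_profile <- function(mean_asynchrony = 0, jitter_sd = 0,
                           miss_prob = 0, extra_rate = 0,
                           wrong_hand_prob = 0, seed = 1L) {
  probs <- c(miss_prob, wrong_hand_prob)
  if (any(probs < 0) || any(probs > 1)) {
    stop("miss_prob and wrong_hand_prob must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(jitter_sd >= 0, extra_rate >= 0)
  structure(
    list(mean_asynchrony = as.numeric(mean_asynchrony),
         jitter_sd = as.numeric(jitter_sd),
         miss_prob = as.numeric(miss_prob),
         extra_rate = as.numeric(extra_rate),
         wrong_hand_prob = as.numeric(wrong_hand_prob),
         seed = as.integer(seed)),
    class = "tapper_profile"
  )
}

#' @rdname tapper_profile
#' @param path JSON file path.
#' @export
read_tapper_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tapper_profile(x$mean_asynchrony, x$jitter_sd, x$miss_prob,
                 x$extra_rate, x$wrong_hand_prob, x$seed)
}

#' @rdname tapper_profile
#' @param profile a `tapper_profile`.
#' @export
write_tapper_profile <- function(profile, path) {
  jsonlite::write_json(unclass(profile), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a tap stream for one timeline
#'
#' Draws one virtual performance of the timeline under the profile's
#' noise model. Taps falling before time zero are clamped to 0 ms
#' (the phase start). The result is fully reproducible from the
#' profile's seed unless `use_seed = FALSE` (used when an outer
#' simulation manages the RNG stream).
#'
#' @param timeline a [target_timeline()].
#' @param profile a [tapper_profile()].
#' @param use_seed reset the RNG from `profile$seed` first (default).
#' @return A [tap_events()] table sorted by timestamp.
#' @export
simulate_taps <- function(timeline, profile, use_seed = TRUE) {
  stopifnot(inherits(timeline, "target_timeline"),
            inherits(profile, "tapper_profile"))
  if (use_seed) set.seed(profile$seed)
  b <- timeline$beats
  n <- nrow(b)
  ts <- numeric(0); drum <- character(0)
  if (n > 0) {
    produced <- stats::runif(n) >= profile$miss_prob
    k <- sum(produced)
    if (k > 0) {
      t_hit <- b$onset_ms[produced] +
        stats::rnorm(k, profile$mean_asynchrony, profile$jitter_sd)
      wrong <- stats::runif(k) < profile$wrong_hand_prob
      h <- b$hand[produced]
      h[wrong] <- other_hand(h[wrong])
      ts <- c(ts, pmax(0, t_hit)); drum <- c(drum, h)
    }
  }
  if (profile$extra_rate > 0) {
    span_ms <- if (n > 0) max(b$onset_ms) + 1000 else 1000
    n_extra <- stats::rpois(1, profile$extra_rate * span_ms / 1000)
    if (n_extra > 0) {
      ts <- c(ts, stats::runif(n_extra, 0, span_ms))
      drum <- c(drum, sample(hand_sides(), n_extra, replace = TRUE))
    }
  }
  ord <- order(ts)
  tap_events(ts[ord], drum[ord])
}

#' Expected accuracy under the tapper noise model
#'
#' Closed form for the session accuracy of a simulated tapper on a
#' timeline whose targets all share one hand and one half-window: a
#' target scores 1 when a tap is produced (prob `1 - miss_prob`), on the
#' correct drum (prob `1 - wrong_hand_prob`), and its Gaussian asynchrony
#' falls inside the window: `P(|N(mu, sigma)| <= half_window)`. On
#' mixed-hand timelines a wrong-drum tap can occasionally rescue a
#' neighbouring opposite-hand target, so the closed form is a slight
#' underestimate there.
#'
#' @param profile a [tapper_profile()].
#' @param half_window_ms the shared half-window in ms.
#' @return Expected accuracy fraction.
#' @export
expected_accuracy <- function(profile, half_window_ms) {
  p_window <- if (profile$jitter_sd == 0) {
    as.numeric(abs(profile$mean_asynchrony) <= half_window_ms)
  } else {
    stats::pnorm(half_window_ms, profile$mean_asynchrony,
                 profile$jitter_sd) -
      stats::pnorm(-half_window_ms, profile$mean_asynchrony,
                   profile$jitter_sd)
  }
  (1 - profile$miss_prob) * (1 - profile$wrong_hand_prob) * p_window
}

#' Simulate a full training program
#'
#' Walks the catalog as a participant would: on each scheduled training
#' day the lowest-index unlocked training session not yet passed at the
#' unlock threshold is played (falling back to the highest unlocked
#' session once everything unlocked has been passed), taps are drawn from
#' the profile, the session is scored, and the progression state updated.
#' Play days follow the behaviour plan: `sessions_per_week` evenly spaced
#' days per week for `weeks` weeks. Deterministic given the profile seed.
#'
#' @param catalog a `program_catalog`.
#' @param profile a [tapper_profile()].
#' @param sessions_per_week planned training days per week.
#' @param weeks program span in weeks.
#' @param start first engagement date (ISO, default `"2026-01-05"`).
#' @param tablet_id device code; generated from the seed when `NULL`.
#' @return A list with `engagement` ([engagement_records()]), `results`
#'   (list of `session_result`), and `state` (final
#'   `progression_state`).
#' @export
simulate_program <- function(catalog, profile, sessions_per_week = 5L,
                             weeks = 8L, start = "2026-01-05",
                             tablet_id = NULL) {
  stopifnot(inherits(catalog, "program_catalog"),
            inherits(profile, "tapper_profile"))
  set.seed(profile$seed)
  if (is.null(tablet_id)) tablet_id <- new_tablet_id()
  state <- initial_state(catalog)
  threshold <- catalog$unlock_threshold
  day_offsets <- unlist(lapply(seq_len(weeks) - 1L, function(w) {
    w * 7 + floor(seq(0, 6, length.out = sessions_per_week))
  }))
  t0 <- as.POSIXct(paste0(start, "T18:00:00Z"),
                   format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  results <- list()
  sess_idx <- integer(0); starts <- character(0); durs <- numeric(0)
  for (d in day_offsets) {
    passed <- as.integer(names(state$best_accuracy))[
      state$best_accuracy >= threshold]
    candidates <- setdiff(setdiff(state$unlocked, 0L), passed)
    play <- if (length(candidates) > 0) min(candidates)
            else max(setdiff(state$unlocked, 0L))
    spec <- catalog_session(catalog, play)
    taps <- simulate_taps(build_timeline(spec), profile, use_seed = FALSE)
    res <- score_session(spec, taps, success_threshold = threshold)
    when <- t0 + d * 86400
    state <- apply_result(state, play, res$summary$mean_accuracy,
                          timestamp = format(when, "%Y-%m-%dT%H:%M:%SZ"))$state
    results[[length(results) + 1L]] <- res
    sess_idx <- c(sess_idx, play)
    starts <- c(starts, format(when, "%Y-%m-%dT%H:%M:%SZ"))
    durs <- c(durs, spec$nominal_duration * 60)
  }
  list(
    engagement = engagement_records(tablet_id, sess_idx, starts, durs),
    results = results,
    state = state
  )
}
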