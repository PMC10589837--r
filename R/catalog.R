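#' Total hit-window width for a tempo
#'
#' The symmetric time window around each expected hit narrows as the
#' training tempo rises: the slowest sessions (below 60 beats/min, i.e.
#' under one beat per second) allow a total window of 1000 ms (500 ms
#' either side of the hit), and sessions faster than 100 beats/min allow
#' only 100 ms. Between the two anchors the width falls linearly with
#' tempo, giving a monotone non-increasing schedule bounded in
#' [100, 1000] ms.
#'
#' @param tempo_bpm tempo in beats per minute, > 0 (vectorised).
#' @return Total window width in ms.
#' @examples
#' window_width_for_tempo(c(55, 80, 110))
#' @export
window_width_for_tempo <- function(tempo_bpm) {
  if (!is.numeric(tempo_bpm) || any(!is.finite(tempo_bpm)) ||
      any(tempo_bpm <= 0)) {
    stop("tempo_bpm must be positive and finite", call. = FALSE)
  }
  w <- 1000 - (tempo_bpm - 60) * (1000 - 100) / (100 - 60)
  pmin(1000, pmax(100, w))
}

#' Construct a session specification
#'
#' A session specification fixes everything needed to derive the session's
#' scoring reference: the rhythm pattern, how many times it cycles through
#' the scored performance phase, and the tempo (which also sets the hit
#' window). Presentation attributes (metronome, background track, phase
#' layout, nominal duration) are carried for catalog bookkeeping.
#'
#' @param index 0 for the introduction, 1..22 for training sessions.
#' @param label display label.
#' @param tempo_bpm tempo in beats/min, positive, at most 117.
#' @param pattern a [rhythm_pattern()].
#' @param n_cycles pattern repetitions in the scored performance phase.
#' @param hands_mode `"separate_then_together"` (sessions 1-7) or
#'   `"both_reversed"` (sessions 8 on).
#' @param has_metronome logical, metronome sounds present.
#' @param background_track_id integer id of the backing track; constant
#'   across each consecutive group of three training sessions.
#' @param phase_layout list of phases, each `list(kind=, cycles=)` with
#'   `kind` in `training`/`performance`.
#' @param nominal_duration nominal session length in minutes (10-15).
#' @return An object of class `session_spec`.
#' @export
session_spec <- function(index, label, tempo_bpm, pattern, n_cycles,
                         hands_mode = c("separate_then_together",
                                        "both_reversed"),
                         has_metronome = TRUE,
                         background_track_id = 1L,
                         phase_layout = NULL,
                         nominal_duration = 12) {
  hands_mode <- match.arg(hands_mode)
  stopifnot(inherits(pattern, "rhythm_pattern"))
  if (!is.numeric(tempo_bpm) || tempo_bpm <= 0 || tempo_bpm > 117) {
    stop("tempo_bpm must be in (0, 117]", call. = FALSE)
  }
  if (n_cycles < 1 || n_cycles != round(n_cycles)) {
    stop("n_cycles must be a whole number >= 1", call. = FALSE)
  }
  if (nominal_duration < 10 || nominal_duration > 15) {
    stop("nominal_duration must lie within 10-15 minutes", call. = FALSE)
  }
  if (is.null(phase_layout)) {
    phase_layout <- list(
      list(kind = "training", cycles = c(1L, as.integer(n_cycles))),
      list(kind = "performance", cycles = c(1L, as.integer(n_cycles)))
    )
  }
  structure(
    list(index = as.integer(index), label = label,
         tempo_bpm = as.numeric(tempo_bpm), pattern = pattern,
         n_cycles = as.integer(n_cycles), hands_mode = hands_mode,
         has_metronome = isTRUE(has_metronome),
         background_track_id = as.integer(background_track_id),
         phase_layout = phase_layout,
         nominal_duration = as.numeric(nominal_duration)),
    class = "session_spec"
  )
}

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf(
    "<session_spec> #%d '%s': %g bpm, %s x %d cycles, %s, %s, track %d\n",
    x$index, x$label, x$tempo_bpm, x$pattern$name, x$n_cycles,
    x$hands_mode, if (x$has_metronome) "metronome" else "no metronome",
    x$background_track_id))
  invisible(x)
}

#' Construct a target timeline
#'
#' The scoring reference for one session: the ordered expected hits, each
#' with an onset (ms from the start of the scored performance phase), a
#' hand, and a half-window (ms) within which a correct-hand tap counts as
#' accurate. Onsets must be strictly increasing and windows pairwise
#' disjoint.
#'
#' @param session_index session the timeline belongs to.
#' @param onsets_ms integer ms onsets, strictly increasing.
#' @param hands hand side per target.
#' @param half_windows_ms half-window per target, ms > 0.
#' @return An object of class `target_timeline` whose `beats` element is a
#'   data.frame with columns `onset_ms`, `hand`, `half_window_ms`.
#' @export
target_timeline <- function(session_index, onsets_ms, hands,
                            half_windows_ms) {
  n <- length(onsets_ms)
  stopifnot(length(hands) == n, length(half_windows_ms) %in% c(1L, n))
  if (n > 0) {
    assert_hand(hands, "timeline hands")
    if (any(onsets_ms < 0) || (n > 1 && any(diff(onsets_ms) <= 0))) {
      stop("onsets must be non-negative and strictly increasing",
           call. = FALSE)
    }
    if (any(half_windows_ms <= 0)) {
      stop("half windows must be positive", call. = FALSE)
    }
  }
  beats <- data.frame(
    onset_ms = as.numeric(onsets_ms),
    hand = as.character(hands),
    half_window_ms = rep_len(as.numeric(half_windows_ms), n),
    stringsAsFactors = FALSE
  )
  tl <- structure(
    list(session_index = as.integer(session_index), beats = beats,
         total_targets = n),
    class = "target_timeline"
  )
  if (n > 1) {
    lo <- beats$onset_ms - beats$half_window_ms
    hi <- beats$onset_ms + beats$half_window_ms
    if (any(hi[-n] >= lo[-1])) {
      stop("target windows overlap; clamp half windows first",
           call. = FALSE)
    }
  }
  tl
}

#' @export
print.target_timeline <- function(x, ...) {
  cat(sprintf("<target_timeline> session %d: %d targets",
              x$session_index, x$total_targets))
  if (x$total_targets > 0) {
    cat(sprintf(", %g-%g ms", min(x$beats$onset_ms), max(x$beats$onset_ms)))
  }
  cat("\n")
  invisible(x)
}

#' Expand a session specification into its target timeline
#'
#' Repeats the session's rhythm pattern `n_cycles` times at the session
#' tempo, producing absolute onsets in integer milliseconds from the start
#' of the scored performance phase (first stroke at 0 ms). Every target
#' receives half the tempo-dependent window width
#' ([window_width_for_tempo()]), then each half-window is clamped to 45%
#' of the smaller adjacent inter-onset interval so that neighbouring
#' windows can never overlap and every tap has at most one owning window.
#'
#' @param spec a [session_spec()].
#' @return A [target_timeline()].
#' @export
build_timeline <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  p <- spec$pattern
  beat_ms <- 60000 / spec$tempo_bpm
  cyc <- rep(seq_len(spec$n_cycles) - 1, each = length(p$beat_offsets))
  offsets_beats <- cyc * p$cycle_length + rep(p$beat_offsets, spec$n_cycles)
  onsets <- round(offsets_beats * beat_ms)
  hands <- rep(p$hands, spec$n_cycles)
  hw <- rep(window_width_for_tempo(spec$tempo_bpm) / 2, length(onsets))
  if (length(onsets) > 1) {
    ioi <- diff(onsets)
    adj <- pmin(c(ioi[1], ioi), c(ioi, ioi[length(ioi)]))  # min adjacent IOI
    hw <- pmin(hw, 0.45 * adj)
  }
  target_timeline(spec$index, onsets, hands, hw)
}

# tempo ramp of the 22 training sessions: starts below 60 bpm (one beat per
# second) and rises monotonically to the program maximum of 117 bpm
catalog_tempos <- function() {
  c(55, 60, 65, 70, 72, 75, 78, 80, 82, 85, 88,
    90, 92, 95, 98, 100, 103, 106, 109, 112, 115, 117)
}

#' The default 1 + 22 session training program
#'
#' Builds the full program catalog: one introduction plus 22 training
#' sessions spanning a monotone tempo ramp from 55 to 117 beats/min with
#' non-decreasing target counts. The first three sessions use slow regular
#' pulses (session 1 tapping on all four beats without a metronome); from
#' session 4 onward the patterns are paradiddle-based. Sessions 1-7 are
#' practiced hand-by-hand then together, later sessions with both hands
#' and then in reverse order. Rhythmic styles and background tracks rotate
#' in groups of three consecutive sessions, and the session-unlock
#' accuracy threshold is 0.70.
#'
#' @param unlock_threshold accuracy fraction required to unlock the next
#'   session, default 0.70.
#' @return An object of class `program_catalog` with elements `sessions`
#'   (introduction first, then training sessions 1..22) and
#'   `unlock_threshold`.
#' @examples
#' cat22 <- default_catalog()
#' length(cat22$sessions)
#' @export
default_catalog <- function(unlock_threshold = 0.70) {
  tempos <- catalog_tempos()
  styles <- c("Hip-Hop", "Funk", "Samba", "Reggaeton")
  sessions <- vector("list", 23L)
  sessions[[1]] <- session_spec(
    index = 0L, label = "Introduction", tempo_bpm = 55,
    pattern = make_pulse(4L, "alternating"), n_cycles = 4L,
    hands_mode = "separate_then_together", has_metronome = FALSE,
    background_track_id = 0L, nominal_duration = 10
  )
  for (s in 1:22) {
    group <- (s - 1L) %/% 3L                 # 3 sessions share one track
    style <- styles[group %% length(styles) + 1L]
    if (s <= 3) {
      pattern <- make_pulse(4L, "alternating")
      n_cycles <- 9L + s                      # 40, 44, 48 targets
      metronome <- s > 1                      # session 1: no metronome
    } else {
      pattern <- make_paradiddle(1L, if (s %% 2 == 0) "right" else "left")
      n_cycles <- s + 3L                      # 8 strokes: 56..200 targets
      metronome <- TRUE
    }
    sessions[[s + 1L]] <- session_spec(
      index = s,
      label = sprintf("Session %d (%s)", s, style),
      tempo_bpm = tempos[s],
      pattern = pattern,
      n_cycles = n_cycles,
      hands_mode = if (s <= 7) "separate_then_together" else "both_reversed",
      has_metronome = metronome,
      background_track_id = group + 1L,
      nominal_duration = round(10 + 5 * (s - 1) / 21, 1)
    )
  }
  structure(
    list(sessions = sessions,
         unlock_threshold = as.numeric(unlock_threshold)),
    class = "program_catalog"
  )
}

#' @export
print.program_catalog <- function(x, ...) {
  tr <- training_sessions(x)
  cat(sprintf(
    "<program_catalog> %d training sessions + introduction, %g-%g bpm, unlock threshold %.0f%%\n",
    length(tr), min(vapply(tr, `[[`, 0, "tempo_bpm")),
    max(vapply(tr, `[[`, 0, "tempo_bpm")), 100 * x$unlock_threshold))
  invisible(x)
}

#' @rdname default_catalog
#' @param catalog a `program_catalog`.
#' @export
training_sessions <- function(catalog) {
  stopifnot(inherits(catalog, "program_catalog"))
  Filter(function(s) s$index >= 1L, catalog$sessions)
}

#' @rdname default_catalog
#' @param index session index (0 = introduction).
#' @export
catalog_session <- function(catalog, index) {
  stopifnot(inherits(catalog, "program_catalog"))
  for (s in catalog$sessions) if (s$index == index) return(s)
  stop(sprintf("no session with index %d in catalog", index), call. = FALSE)
}

#' Catalog overview table
#'
#' One row per session with the attributes that define difficulty:
#' tempo, pattern, target count and window width.
#'
#' @param catalog a `program_catalog`.
#' @return A data.frame, introduction first.
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "program_catalog"))
  rows <- lapply(catalog$sessions, function(s) {
    tl <- build_timeline(s)
    data.frame(
      index = s$index, label = s$label, tempo_bpm = s$tempo_bpm,
      pattern = s$pattern$name, n_cycles = s$n_cycles,
      total_targets = tl$total_targets,
      window_ms = window_width_for_tempo(s$tempo_bpm),
      hands_mode = s$hands_mode, metronome = s$has_metronome,
      background_track_id = s$background_track_id,
      nominal_duration_min = s$nominal_duration,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Validate a program catalog's structural invariants
#'
#' Checks the program shape: exactly one introduction and 22 training
#' sessions; tempos positive, capped at 117 bpm and non-decreasing over
#' the training index; target counts non-decreasing; hands mode switching
#' at session 8; background tracks constant across each group of three;
#' and pairwise-disjoint hit windows in every derived timeline.
#'
#' @param catalog a `program_catalog`.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "program_catalog"))
  idx <- vapply(catalog$sessions, `[[`, 0L, "index")
  if (sum(idx == 0L) != 1L || !setequal(idx[idx > 0], 1:22)) {
    stop("catalog must hold exactly 1 introduction and training sessions 1..22",
         call. = FALSE)
  }
  tr <- training_sessions(catalog)
  tr <- tr[order(vapply(tr, `[[`, 0L, "index"))]
  tempos <- vapply(tr, `[[`, 0, "tempo_bpm")
  if (any(diff(tempos) < 0) || max(tempos) > 117) {
    stop("training tempos must be non-decreasing and at most 117 bpm",
         call. = FALSE)
  }
  timelines <- lapply(tr, build_timeline)   # constructor rejects overlaps
  targets <- vapply(timelines, `[[`, 0L, "total_targets")
  if (any(diff(targets) < 0)) {
    stop("target counts must be non-decreasing over training sessions",
         call. = FALSE)
  }
  for (s in tr) {
    want <- if (s$index <= 7) "separate_then_together" else "both_reversed"
    if (s$hands_mode != want) {
      stop(sprintf("session %d must use hands_mode '%s'", s$index, want),
           call. = FALSE)
    }
  }
  track <- vapply(tr, `[[`, 0L, "background_track_id")
  grp <- (vapply(tr, `[[`, 0L, "index") - 1L) %/% 3L
  if (any(tapply(track, grp, function(v) length(unique(v))) != 1L)) {
    stop("background track must be constant within each group of 3 sessions",
         call. = FALSE)
  }
  invisible(TRUE)
}
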