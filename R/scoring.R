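#' Construct a tap-event table
#'
#' Tap events are the raw behavioural data: one screen tap per row, with a
#' phase-relative timestamp in ms and the drum (hand side) that was hit.
#' Input order is irrelevant; the scorer sorts stably by timestamp.
#'
#' @param timestamp_ms numeric timestamps in ms, >= 0.
#' @param drum hand side per tap (`"left"` / `"right"`).
#' @return A data.frame of class `tap_events` with columns `timestamp_ms`
#'   and `drum`.
#' @export
tap_events <- function(timestamp_ms = numeric(0), drum = character(0)) {
  stopifnot(length(timestamp_ms) == length(drum))
  if (length(drum) > 0) assert_hand(drum, "drum")
  if (any(timestamp_ms < 0)) {
    stop("tap timestamps must be non-negative", call. = FALSE)
  }
  structure(
    data.frame(timestamp_ms = as.numeric(timestamp_ms),
               drum = as.character(drum), stringsAsFactors = FALSE),
    class = c("tap_events", "data.frame")
  )
}

#' Read / write tap logs
#'
#' Tap logs are plain CSV with header `timestamp_ms,drum`.
#'
#' @param path CSV file path.
#' @return `read_tap_log` returns a [tap_events()] table.
#' @export
read_tap_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("timestamp_ms", "drum") %in% names(df))) {
    stop(sprintf("'%s' is not a tap log: need columns timestamp_ms,drum",
                 path), call. = FALSE)
  }
  tap_events(df$timestamp_ms, df$drum)
}

#' @rdname read_tap_log
#' @param taps a [tap_events()] table.
#' @export
write_tap_log <- function(taps, path) {
  utils::write.csv(as.data.frame(taps)[c("timestamp_ms", "drum")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match tap events to target beats
#'
#' Implements the accuracy rule: a target scores 1 only if a tap on the
#' correct drum falls inside the target's symmetric window
#' `[onset - half_window, onset + half_window]`. Because windows are
#' pairwise disjoint, each tap can lie in at most one window; among the
#' correct-drum taps inside a target's window the one with smallest
#' absolute latency is matched (ties going to the earlier tap). Latency is
#' signed: `tap - onset`, positive when the tap is late. Every input tap
#' is classified exactly once, either as a matched tap or as an extra tap
#' (`surplus_in_window`, `wrong_drum_in_window`, or
#' `outside_all_windows`); extras always carry accuracy 0.
#'
#' @param timeline a [target_timeline()] with pairwise-disjoint windows.
#' @param taps a [tap_events()] table (any row order).
#' @return A list with elements `records` (one row per target:
#'   `target_index`, `hand`, `onset_ms`, `half_window_ms`, `accuracy`,
#'   `latency_ms` (NA when unmatched), `tap_timestamp_ms`) and `extras`
#'   (one row per unmatched tap: `timestamp_ms`, `drum`, `classification`,
#'   `accuracy`).
#' @export
match_taps <- function(timeline, taps) {
  stopifnot(inherits(timeline, "target_timeline"))
  if (!inherits(taps, "tap_events")) taps <- tap_events(taps$timestamp_ms,
                                                        taps$drum)
  b <- timeline$beats
  n_t <- nrow(b)
  ord <- order(taps$timestamp_ms)          # stable sort
  ts <- taps$timestamp_ms[ord]
  drum <- taps$drum[ord]
  n_taps <- length(ts)
  if (n_t > 1) {
    lo <- b$onset_ms - b$half_window_ms
    hi <- b$onset_ms + b$half_window_ms
    if (any(hi[-n_t] >= lo[-1])) {
      stop("internal inconsistency: timeline windows overlap", call. = FALSE)
    }
  }

  matched_tap <- rep(NA_integer_, n_t)     # tap row (sorted order) per target
  # owning window per tap: the unique target whose window contains the tap
  owner <- rep(NA_integer_, n_taps)
  if (n_t > 0 && n_taps > 0) {
    cand <- findInterval(ts, b$onset_ms - b$half_window_ms)
    inside <- cand >= 1 &
      ts <= (b$onset_ms[pmax(cand, 1)] + b$half_window_ms[pmax(cand, 1)])
    owner[inside] <- cand[inside]
    for (j in seq_len(n_t)) {
      in_win <- which(owner == j & drum == b$hand[j])
      if (length(in_win) > 0) {
        lat <- abs(ts[in_win] - b$onset_ms[j])
        # min |latency|; ties go to the earlier tap (lower sorted position)
        matched_tap[j] <- in_win[which.min(lat)]
      }
    }
  }

  accuracy <- as.integer(!is.na(matched_tap))
  latency <- rep(NA_real_, n_t)
  tap_ts <- rep(NA_real_, n_t)
  hit <- which(accuracy == 1L)
  latency[hit] <- ts[matched_tap[hit]] - b$onset_ms[hit]
  tap_ts[hit] <- ts[matched_tap[hit]]
  records <- data.frame(
    target_index = seq_len(n_t), hand = b$hand, onset_ms = b$onset_ms,
    half_window_ms = b$half_window_ms, accuracy = accuracy,
    latency_ms = latency, tap_timestamp_ms = tap_ts,
    stringsAsFactors = FALSE
  )

  leftover <- setdiff(seq_len(n_taps), matched_tap[hit])
  classification <- character(length(leftover))
  for (k in seq_along(leftover)) {
    i <- leftover[k]
    j <- owner[i]
    classification[k] <-
      if (is.na(j)) "outside_all_windows"
      else if (drum[i] == b$hand[j]) "surplus_in_window"
      else "wrong_drum_in_window"
  }
  extras <- data.frame(
    timestamp_ms = ts[leftover], drum = drum[leftover],
    classification = classification,
    accuracy = rep(0L, length(leftover)),
    stringsAsFactors = FALSE
  )
  list(records = records, extras = extras)
}

#' Session summary statistics
#'
#' The eight per-session summary statistics: mean tap response latency and
#' accuracy overall and per hand, and the minimum (best) absolute latency
#' per hand. Accuracy is the fraction of target beats scored 1, so it
#' always lies in [0, 1]; extra taps are logged but never enter the
#' denominator. Latency statistics are computed over accurate taps only
#' and are `NA` (never 0) when no accurate tap exists for the relevant
#' hand.
#'
#' @param records,extras output of [match_taps()].
#' @param timeline the matching [target_timeline()].
#' @return A one-row data.frame of class `session_summary` with columns
#'   `mean_latency_ms`, `mean_accuracy`, `mean_left_latency_ms`,
#'   `mean_right_latency_ms`, `min_left_latency_ms`,
#'   `min_right_latency_ms`, `mean_left_accuracy`, `mean_right_accuracy`.
#' @export
summarize_session <- function(records, extras, timeline) {
  stopifnot(inherits(timeline, "target_timeline"))
  if (timeline$total_targets == 0L) {
    stop("cannot summarise a session with zero target beats", call. = FALSE)
  }
  if (nrow(records) != timeline$total_targets) {
    stop("records must contain exactly one row per target", call. = FALSE)
  }
  lat <- records$latency_ms
  acc <- records$accuracy
  hand <- records$hand
  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  min_or_na <- function(x) if (length(x) == 0) NA_real_ else min(x)
  hand_lat <- function(h) lat[hand == h & acc == 1L]
  out <- data.frame(
    mean_latency_ms = mean_or_na(lat[acc == 1L]),
    mean_accuracy = mean(acc),
    mean_left_latency_ms = mean_or_na(hand_lat("left")),
    mean_right_latency_ms = mean_or_na(hand_lat("right")),
    min_left_latency_ms = min_or_na(abs(hand_lat("left"))),
    min_right_latency_ms = min_or_na(abs(hand_lat("right"))),
    mean_left_accuracy = mean_or_na(acc[hand == "left"]),
    mean_right_accuracy = mean_or_na(acc[hand == "right"])
  )
  class(out) <- c("session_summary", "data.frame")
  out
}

#' Score a session's tap log
#'
#' Composes the full scoring pipeline for one session: expand the
#' specification into its target timeline, match the taps, and summarise.
#' The result carries the difficulty metadata logged with every session:
#' total number of target beats, the allowed window duration (ms) at the
#' session tempo, and the success accuracy threshold (%).
#'
#' @param spec a [session_spec()].
#' @param taps a [tap_events()] table.
#' @param success_threshold unlock accuracy threshold as a fraction
#'   (default 0.70).
#' @return An object of class `session_result`: list with
#'   `session_index`, `records`, `extras`, `summary`, and `metadata`
#'   (`total_targets`, `window_duration_ms`, `success_threshold_pct`).
#' @export
score_session <- function(spec, taps, success_threshold = 0.70) {
  stopifnot(inherits(spec, "session_spec"))
  timeline <- build_timeline(spec)
  score_timeline(timeline, taps, tempo_bpm = spec$tempo_bpm,
                 success_threshold = success_threshold)
}

#' @rdname score_session
#' @param timeline a [target_timeline()]; used when scoring against an
#'   externally supplied (e.g. MIDI-read) reference.
#' @param tempo_bpm session tempo, used for the window-duration metadatum.
#' @export
score_timeline <- function(timeline, taps, tempo_bpm,
                           success_threshold = 0.70) {
  m <- match_taps(timeline, taps)
  summary <- summarize_session(m$records, m$extras, timeline)
  structure(
    list(session_index = timeline$session_index,
         records = m$records, extras = m$extras, summary = summary,
         metadata = list(
           total_targets = timeline$total_targets,
           window_duration_ms = window_width_for_tempo(tempo_bpm),
           success_threshold_pct = 100 * success_threshold)),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf(
    "<session_result> session %d: accuracy %.1f%% over %d targets, %d extra taps\n",
    x$session_index, 100 * x$summary$mean_accuracy,
    x$metadata$total_targets, nrow(x$extras)))
  if (!is.na(x$summary$mean_latency_ms)) {
    cat(sprintf("  mean latency %+.1f ms (window %g ms)\n",
                x$summary$mean_latency_ms, x$metadata$window_duration_ms))
  }
  invisible(x)
}
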