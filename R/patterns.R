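#' Hand sides
#'
#' The two drums on the tablet screen map to the two hands: the left
#' triangle drum carries the high-pitch bongo sound, the right circle drum
#' the low-pitch sound. All pattern, timeline and tap structures encode the
#' hand as the character constants `"left"` / `"right"`.
#'
#' @return Character vector of the two valid hand labels.
#' @export
hand_sides <- function() c("left", "right")

#' @rdname hand_sides
#' @param hand character vector to validate.
#' @export
is_hand_side <- function(hand) {
  is.character(hand) && all(hand %in% hand_sides())
}

assert_hand <- function(hand, what = "hand") {
  if (!is_hand_side(hand)) {
    stop(sprintf("invalid %s: must be 'left' or 'right'", what), call. = FALSE)
  }
  hand
}

other_hand <- function(hand) {
  ifelse(hand == "left", "right", "left")
}

#' Construct a rhythm pattern
#'
#' A rhythm pattern is one cycle of strokes, each at a beat offset (in
#' beats from the start of the cycle) on one hand. Offsets must be strictly
#' increasing and lie inside the cycle.
#'
#' @param name pattern label.
#' @param beat_offsets numeric vector of stroke positions in beats, >= 0.
#' @param hands character vector of hand sides, same length as
#'   `beat_offsets`.
#' @param cycle_length cycle length in beats, > 0.
#' @return An object of class `rhythm_pattern`.
#' @export
rhythm_pattern <- function(name, beat_offsets, hands, cycle_length) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(beat_offsets) != length(hands)) {
    stop("beat_offsets and hands must have equal length", call. = FALSE)
  }
  assert_hand(hands, "pattern hands")
  if (length(beat_offsets) == 0L) {
    stop("a rhythm pattern needs at least one stroke", call. = FALSE)
  }
  if (any(beat_offsets < 0) || any(diff(beat_offsets) <= 0)) {
    stop("beat_offsets must be non-negative and strictly increasing",
         call. = FALSE)
  }
  if (!is.numeric(cycle_length) || cycle_length <= 0 ||
      any(beat_offsets >= cycle_length)) {
    stop("cycle_length must be positive and exceed every beat_offset",
         call. = FALSE)
  }
  structure(
    list(name = name,
         beat_offsets = as.numeric(beat_offsets),
         hands = as.character(hands),
         cycle_length = as.numeric(cycle_length)),
    class = "rhythm_pattern"
  )
}

#' @export
print.rhythm_pattern <- function(x, ...) {
  cat(sprintf("<rhythm_pattern> %s: %d strokes / %g beats\n",
              x$name, length(x$hands), x$cycle_length))
  cat(" ", paste(sprintf("%s@%g", toupper(substr(x$hands, 1, 1)),
                         x$beat_offsets), collapse = " "), "\n")
  invisible(x)
}

#' Eight-stroke paradiddle pattern
#'
#' The paradiddle is the drum rudiment in which a single tap is followed by
#' a double tap; with a right lead one full cycle reads
#' R L R R L R L L, the leading hand alternating every four strokes.
#' Strokes fall at half-beat (eighth-note) spacing, so a cycle spans four
#' beats. `n_cycles` repeats extend the pattern; the repeated cycles are
#' identical.
#'
#' @param n_cycles number of 8-stroke cycles, >= 1.
#' @param lead leading hand, `"right"` (default) or `"left"`.
#' @return A `rhythm_pattern` of `8 * n_cycles` strokes over
#'   `4 * n_cycles` beats.
#' @examples
#' make_paradiddle(1, "right")$hands
#' @export
make_paradiddle <- function(n_cycles = 1L, lead = "right") {
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    stop("n_cycles must be a whole number >= 1", call. = FALSE)
  }
  assert_hand(lead, "lead")
  a <- lead
  b <- other_hand(lead)
  cycle <- c(a, b, a, a, b, a, b, b)
  hands <- rep(cycle, n_cycles)
  offsets <- seq_along(hands) / 2 - 0.5  # eighth notes: 0, 0.5, 1, ...
  rhythm_pattern(
    name = sprintf("paradiddle_%s_lead", lead),
    beat_offsets = offsets,
    hands = hands,
    cycle_length = 4 * n_cycles
  )
}

#' Regular pulse pattern
#'
#' One stroke per beat on a single hand (or alternating hands), the simple
#' rhythm used by the slow opening sessions in which participants tap on
#' all four beats of the bar.
#'
#' @param beats_per_cycle strokes (and beats) per cycle.
#' @param hand a single hand, or `"alternating"`.
#' @return A `rhythm_pattern`.
#' @export
make_pulse <- function(beats_per_cycle = 4L, hand = "right") {
  stopifnot(beats_per_cycle >= 1)
  hands <- if (identical(hand, "alternating")) {
    rep_len(c("right", "left"), beats_per_cycle)
  } else {
    rep(assert_hand(hand), beats_per_cycle)
  }
  rhythm_pattern(
    name = sprintf("pulse_%d_%s", beats_per_cycle,
                   if (identical(hand, "alternating")) "alt" else hand),
    beat_offsets = seq_len(beats_per_cycle) - 1,
    hands = hands,
    cycle_length = beats_per_cycle
  )
}
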