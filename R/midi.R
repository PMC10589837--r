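# Standard MIDI File (format 0) I/O for target timelines.
#
# Dialect: one track, PPQ 480, a single tempo meta-event fixed at
# 480000 us/quarter so that one tick is exactly one millisecond and onsets
# round-trip bit-exactly. Left-hand targets use note 60 (high-pitch drum),
# right-hand targets note 45 (low-pitch drum). Half-windows are not
# representable in MIDI; they travel in a JSON sidecar next to the file
# (<file>.json) holding the session tempo, and are rebuilt on read from
# that tempo and the read onsets.

MIDI_PPQ <- 480L
MIDI_TEMPO_US <- 480000L   # us per quarter note; 480 ticks/qn -> 1 tick = 1 ms
MIDI_NOTE_LEFT <- 60L
MIDI_NOTE_RIGHT <- 45L
MIDI_NOTE_MS <- 100L       # nominal note duration written before note-off

ms_to_ticks <- function(ms) as.integer(round(ms))
ticks_to_ms <- function(ticks) as.numeric(ticks)

# variable-length quantity encoding (7 bits per byte, high bit = continue)
encode_vlq <- function(value) {
  stopifnot(value >= 0)
  bytes <- as.integer(value %% 128L)
  value <- value %/% 128L
  while (value > 0) {
    bytes <- c(as.integer(value %% 128L) + 128L, bytes)
    value <- value %/% 128L
  }
  as.raw(bytes)
}

uint32_be <- function(x) {
  as.raw(c(x %/% 16777216L, (x %/% 65536L) %% 256L,
           (x %/% 256L) %% 256L, x %% 256L))
}

uint16_be <- function(x) as.raw(c(x %/% 256L, x %% 256L))

#' Write a target timeline as a standard MIDI file
#'
#' Serialises the timeline as a single-track (format 0) MIDI file: each
#' target becomes a note-on/note-off pair at its onset, with note 60 for
#' the left hand and note 45 for the right. The tick clock is fixed at one
#' tick per millisecond so onsets survive the round trip exactly. The
#' half-windows, which MIDI cannot carry, are written to a JSON sidecar
#' (`<destination>.json`) as the session tempo from which
#' [read_target_midi()] reconstructs them.
#'
#' @param timeline a [target_timeline()].
#' @param destination path of the `.mid` file to write.
#' @param tempo_bpm session tempo stored in the sidecar for half-window
#'   reconstruction.
#' @return Invisibly, `destination`.
#' @export
write_target_midi <- function(timeline, destination, tempo_bpm = NULL) {
  stopifnot(inherits(timeline, "target_timeline"))
  b <- timeline$beats
  # events: (tick, type on/off, note); note-off written MIDI_NOTE_MS later
  ev_tick <- integer(0); ev_on <- logical(0); ev_note <- integer(0)
  if (nrow(b) > 0) {
    on_t <- ms_to_ticks(b$onset_ms)
    note <- ifelse(b$hand == "left", MIDI_NOTE_LEFT, MIDI_NOTE_RIGHT)
    ev_tick <- c(on_t, on_t + MIDI_NOTE_MS)
    ev_on <- c(rep(TRUE, nrow(b)), rep(FALSE, nrow(b)))
    ev_note <- c(note, note)
    ord <- order(ev_tick, !ev_on)   # note-offs before note-ons at same tick
    ev_tick <- ev_tick[ord]; ev_on <- ev_on[ord]; ev_note <- ev_note[ord]
  }
  track <- c(
    encode_vlq(0L), as.raw(c(0xFF, 0x51, 0x03)),
    as.raw(c(MIDI_TEMPO_US %/% 65536L, (MIDI_TEMPO_US %/% 256L) %% 256L,
             MIDI_TEMPO_US %% 256L))
  )
  last <- 0L
  for (i in seq_along(ev_tick)) {
    track <- c(track, encode_vlq(ev_tick[i] - last))
    status <- if (ev_on[i]) 0x99 else 0x89      # channel 10 (percussion)
    vel <- if (ev_on[i]) 100L else 0L
    track <- c(track, as.raw(c(status, ev_note[i], vel)))
    last <- ev_tick[i]
  }
  track <- c(track, encode_vlq(0L), as.raw(c(0xFF, 0x2F, 0x00)))
  out <- c(
    charToRaw("MThd"), uint32_be(6L), uint16_be(0L), uint16_be(1L),
    uint16_be(MIDI_PPQ),
    charToRaw("MTrk"), uint32_be(length(track)), track
  )
  writeBin(out, destination)
  sidecar <- list(session_index = timeline$session_index,
                  format = "drumtrainr-midi-sidecar-1")
  if (!is.null(tempo_bpm)) sidecar$tempo_bpm <- as.numeric(tempo_bpm)
  jsonlite::write_json(sidecar, paste0(destination, ".json"),
                       auto_unbox = TRUE)
  invisible(destination)
}

read_vlq <- function(bytes, pos) {
  value <- 0L
  repeat {
    b <- as.integer(bytes[pos]); pos <- pos + 1L
    value <- value * 128L + (b %% 128L)
    if (b < 128L) break
  }
  list(value = value, pos = pos)
}

#' Read a target timeline back from a MIDI file
#'
#' Parses a single-track MIDI file written by [write_target_midi()] (or
#' any format-0 file using only the two drum note numbers 60/left and
#' 45/right): note-on events with positive velocity become target onsets.
#' Half-windows are reconstructed from the session tempo — taken from the
#' JSON sidecar when present, else from `tempo_bpm` — via
#' [window_width_for_tempo()] with the same 45%-of-IOI overlap clamp used
#' by [build_timeline()]. A note number other than 60 or 45 is a format
#' error naming the offending event.
#'
#' @param source path of the `.mid` file.
#' @param tempo_bpm fallback session tempo if no sidecar is found.
#' @return A [target_timeline()].
#' @export
read_target_midi <- function(source, tempo_bpm = NULL) {
  bytes <- readBin(source, "raw", n = file.size(source))
  if (length(bytes) < 14 || rawToChar(bytes[1:4]) != "MThd") {
    stop(sprintf("'%s' is not a standard MIDI file (missing MThd)", source),
         call. = FALSE)
  }
  ntrks <- as.integer(bytes[11]) * 256L + as.integer(bytes[12])
  if (ntrks != 1L) {
    stop(sprintf("expected a single-track MIDI file, found %d tracks", ntrks),
         call. = FALSE)
  }
  pos <- 15L
  if (rawToChar(bytes[pos:(pos + 3L)]) != "MTrk") {
    stop("malformed MIDI file: missing MTrk chunk", call. = FALSE)
  }
  pos <- pos + 8L
  tick <- 0L
  onsets <- numeric(0); hands <- character(0)
  running <- NA_integer_
  repeat {
    v <- read_vlq(bytes, pos); pos <- v$pos; tick <- tick + v$value
    status <- as.integer(bytes[pos])
    if (status >= 128L) { running <- status; pos <- pos + 1L }
    else status <- running
    hi <- status %/% 16L
    if (status == 255L) {               # meta event
      type <- as.integer(bytes[pos]); pos <- pos + 1L
      lenv <- read_vlq(bytes, pos); pos <- lenv$pos + lenv$value
      if (type == 47L) break            # end of track
    } else if (hi %in% c(8L, 9L)) {     # note off / note on
      note <- as.integer(bytes[pos]); vel <- as.integer(bytes[pos + 1L])
      pos <- pos + 2L
      if (hi == 9L && vel > 0L) {
        hand <- if (note == MIDI_NOTE_LEFT) "left"
                else if (note == MIDI_NOTE_RIGHT) "right"
                else stop(sprintf(
                  "unknown note number %d at tick %d: expected %d (left) or %d (right)",
                  note, tick, MIDI_NOTE_LEFT, MIDI_NOTE_RIGHT), call. = FALSE)
        onsets <- c(onsets, ticks_to_ms(tick)); hands <- c(hands, hand)
      }
    } else if (hi %in% c(10L, 11L, 14L)) {
      pos <- pos + 2L                   # two-byte channel messages
    } else if (hi %in% c(12L, 13L)) {
      pos <- pos + 1L                   # one-byte channel messages
    } else {
      stop(sprintf("unsupported MIDI status byte 0x%02X at tick %d",
                   status, tick), call. = FALSE)
    }
    if (pos > length(bytes)) {
      stop("malformed MIDI file: track ended without end-of-track meta event",
           call. = FALSE)
    }
  }
  session_index <- -1L
  sidecar_path <- paste0(source, ".json")
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path)
    if (!is.null(sidecar$tempo_bpm) && is.null(tempo_bpm)) {
      tempo_bpm <- sidecar$tempo_bpm
    }
    if (!is.null(sidecar$session_index)) {
      session_index <- as.integer(sidecar$session_index)
    }
  }
  n <- length(onsets)
  if (n == 0) return(target_timeline(session_index, numeric(0),
                                     character(0), numeric(0)))
  if (is.null(tempo_bpm)) {
    stop("no session tempo available (no sidecar and tempo_bpm missing); cannot reconstruct half windows",
         call. = FALSE)
  }
  hw <- rep(window_width_for_tempo(tempo_bpm) / 2, n)
  if (n > 1) {
    ioi <- diff(onsets)
    adj <- pmin(c(ioi[1], ioi), c(ioi, ioi[length(ioi)]))
    hw <- pmin(hw, 0.45 * adj)
  }
  target_timeline(session_index, onsets, hands, hw)
}
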