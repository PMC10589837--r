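# JSON serialisation of the program catalog, so the session ramp can be
# reconfigured without touching code.

spec_to_list <- function(s) {
  list(index = s$index, label = s$label, tempo_bpm = s$tempo_bpm,
       pattern = list(name = s$pattern$name,
                      beat_offsets = s$pattern$beat_offsets,
                      hands = s$pattern$hands,
                      cycle_length = s$pattern$cycle_length),
       n_cycles = s$n_cycles, hands_mode = s$hands_mode,
       has_metronome = s$has_metronome,
       background_track_id = s$background_track_id,
       phase_layout = s$phase_layout,
       nominal_duration = s$nominal_duration)
}

spec_from_list <- function(x) {
  session_spec(
    index = x$index, label = x$label, tempo_bpm = x$tempo_bpm,
    pattern = rhythm_pattern(x$pattern$name,
                             unlist(x$pattern$beat_offsets),
                             unlist(x$pattern$hands),
                             x$pattern$cycle_length),
    n_cycles = x$n_cycles, hands_mode = x$hands_mode,
    has_metronome = x$has_metronome,
    background_track_id = x$background_track_id,
    phase_layout = lapply(x$phase_layout, function(p) {
      list(kind = p$kind, cycles = as.integer(unlist(p$cycles)))
    }),
    nominal_duration = x$nominal_duration
  )
}

#' Read / write a program catalog as JSON
#'
#' @param catalog a `program_catalog`.
#' @param path JSON file path.
#' @export
write_catalog_json <- function(catalog, path) {
  stopifnot(inherits(catalog, "program_catalog"))
  jsonlite::write_json(
    list(unlock_threshold = catalog$unlock_threshold,
         sessions = lapply(catalog$sessions, spec_to_list)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_catalog_json
#' @export
read_catalog_json <- function(path) {
  x <- jsonlite::read_json(path)
  structure(
    list(sessions = lapply(x$sessions, spec_from_list),
         unlock_threshold = as.numeric(x$unlock_threshold)),
    class = "program_catalog"
  )
}
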