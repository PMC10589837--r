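#' Generate a tablet identifier
#'
#' Output files carry no personal identifiers; devices are coded by a
#' random 16-character string over A-Z and 0-9 (a 36^16 space, so
#' collisions are negligible at study scale). Deterministic under the
#' session RNG seed.
#'
#' @param n number of ids to draw.
#' @return Character vector of 16-character codes.
#' @examples
#' set.seed(1); new_tablet_id()
#' @export
new_tablet_id <- function(n = 1L) {
  alphabet <- c(LETTERS, 0:9)
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, 16L, replace = TRUE), collapse = "")
  }, character(1))
}

# ISO 8601 with "T" separator and optional trailing "Z"; POSIXct inputs
# pass through. base as.POSIXct would silently drop the time-of-day part.
parse_iso8601 <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(sub("Z$", "", sub("T", " ", x)), tz = "UTC")
  if (any(is.na(out) & !is.na(x))) {
    stop("timestamps must be ISO 8601 (YYYY-MM-DDTHH:MM:SSZ)", call. = FALSE)
  }
  out
}

assert_tablet_id <- function(id) {
  if (!is.character(id) || any(nchar(id) != 16L) ||
      any(!grepl("^[A-Z0-9]{16}$", id))) {
    stop("tablet_id must be a 16-character A-Z/0-9 code", call. = FALSE)
  }
  id
}

#' Engagement records
#'
#' One row per training engagement: the coded tablet id, the session
#' played, the ISO 8601 start time, and the engagement duration in
#' seconds.
#'
#' @param tablet_id 16-character device code(s).
#' @param session_index session played.
#' @param start ISO 8601 start timestamps (character or POSIXct).
#' @param duration_s engagement duration in seconds, > 0.
#' @return A data.frame of class `engagement_records`.
#' @export
engagement_records <- function(tablet_id = character(0),
                               session_index = integer(0),
                               start = character(0),
                               duration_s = numeric(0)) {
  n <- length(session_index)
  stopifnot(length(start) == n, length(duration_s) == n)
  if (n > 0) {
    assert_tablet_id(rep_len(tablet_id, n))
    if (any(duration_s <= 0)) {
      stop("duration_s must be positive", call. = FALSE)
    }
  }
  structure(
    data.frame(tablet_id = rep_len(as.character(tablet_id), n),
               session_index = as.integer(session_index),
               start = format(parse_iso8601(start), "%Y-%m-%dT%H:%M:%SZ"),
               duration_s = as.numeric(duration_s),
               stringsAsFactors = FALSE),
    class = c("engagement_records", "data.frame")
  )
}

#' Read / write engagement logs
#'
#' Plain CSV with header `tablet_id,session_index,start_iso8601,duration_s`.
#'
#' @param path CSV file path.
#' @export
read_engagement_log <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(tablet_id = "character"))
  need <- c("tablet_id", "session_index", "start_iso8601", "duration_s")
  if (!all(need %in% names(df))) {
    stop(sprintf("'%s' is not an engagement log: need columns %s",
                 path, paste(need, collapse = ",")), call. = FALSE)
  }
  engagement_records(df$tablet_id, df$session_index, df$start_iso8601,
                     df$duration_s)
}

#' @rdname read_engagement_log
#' @param records an [engagement_records()] table.
#' @export
write_engagement_log <- function(records, path) {
  out <- data.frame(tablet_id = records$tablet_id,
                    session_index = records$session_index,
                    start_iso8601 = records$start,
                    duration_s = records$duration_s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Training prescription
#'
#' The prescribed home-training dose: approximately 10-15 minutes per
#' day, 5 sessions per week, for 8 weeks.
#'
#' @param minutes_per_day_min,minutes_per_day_max daily practice range in
#'   minutes.
#' @param sessions_per_week prescribed weekly session count.
#' @param weeks program length in weeks.
#' @return An object of class `prescription`.
#' @export
prescription <- function(minutes_per_day_min = 10,
                         minutes_per_day_max = 15,
                         sessions_per_week = 5L,
                         weeks = 8L) {
  stopifnot(minutes_per_day_min > 0,
            minutes_per_day_max >= minutes_per_day_min,
            sessions_per_week > 0, weeks > 0)
  structure(
    list(minutes_per_day = c(minutes_per_day_min, minutes_per_day_max),
         sessions_per_week = as.integer(sessions_per_week),
         weeks = as.integer(weeks)),
    class = "prescription"
  )
}

#' Quantify adherence against the prescription
#'
#' Rolls the engagement log up into weekly counts and minutes, using
#' rolling 7-day windows anchored at the first engagement (a home program
#' starts on an arbitrary day, so calendar/ISO weeks would misalign the
#' dose). The adherence fraction is attended / planned sessions, where
#' planned = `sessions_per_week * weeks`; it is reported as computed, not
#' clipped at 1.
#'
#' @param records an [engagement_records()] table sharing one tablet_id.
#' @param rx a [prescription()].
#' @return An object of class `adherence_report`: list with `tablet_id`,
#'   `weekly` (data.frame: `week`, `sessions`, `minutes`),
#'   `total_sessions`, `total_minutes`, `planned_sessions`,
#'   `adherence_fraction`, and `span_days` (first to last engagement).
#' @export
adherence_summary <- function(records, rx = prescription()) {
  stopifnot(inherits(rx, "prescription"))
  planned <- rx$sessions_per_week * rx$weeks
  if (nrow(records) == 0) {
    return(structure(
      list(tablet_id = NA_character_,
           weekly = data.frame(week = integer(0), sessions = integer(0),
                               minutes = numeric(0)),
           total_sessions = 0L, total_minutes = 0,
           planned_sessions = planned, adherence_fraction = 0,
           span_days = 0),
      class = "adherence_report"
    ))
  }
  ids <- unique(records$tablet_id)
  if (length(ids) != 1L) {
    stop(sprintf("records mix %d tablet ids; adherence is per device",
                 length(ids)), call. = FALSE)
  }
  t0 <- parse_iso8601(records$start)
  days <- as.numeric(difftime(t0, min(t0), units = "days"))
  week <- as.integer(days %/% 7) + 1L
  weekly <- data.frame(
    week = sort(unique(week)),
    sessions = as.integer(tapply(week, week, length)),
    minutes = as.numeric(tapply(records$duration_s / 60, week, sum)),
    row.names = NULL
  )
  structure(
    list(tablet_id = ids,
         weekly = weekly,
         total_sessions = nrow(records),
         total_minutes = sum(records$duration_s) / 60,
         planned_sessions = planned,
         adherence_fraction = nrow(records) / planned,
         span_days = max(days)),
    class = "adherence_report"
  )
}

#' @export
print.adherence_report <- function(x, ...) {
  cat(sprintf(
    "<adherence_report> %s: %d/%d sessions (%.0f%%), %.0f min over %.1f days\n",
    if (is.na(x$tablet_id)) "(no data)" else x$tablet_id,
    x$total_sessions, x$planned_sessions, 100 * x$adherence_fraction,
    x$total_minutes, x$span_days))
  invisible(x)
}

#' @rdname adherence_summary
#' @param report an `adherence_report`.
#' @param path JSON file path.
#' @export
write_adherence_report <- function(report, path) {
  stopifnot(inherits(report, "adherence_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname adherence_summary
#' @export
read_adherence_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$weekly <- as.data.frame(x$weekly)
  if (nrow(x$weekly) == 0) {
    x$weekly <- data.frame(week = integer(0), sessions = integer(0),
                           minutes = numeric(0))
  }
  if (is.null(x$tablet_id)) x$tablet_id <- NA_character_
  structure(x[c("tablet_id", "weekly", "total_sessions", "total_minutes",
                "planned_sessions", "adherence_fraction", "span_days")],
            class = "adherence_report")
}
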