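# The per-session output file: RFC 4180 CSV, UTF-8, one logical record
# per row, missing values as empty fields. Four blocks share one column
# set, discriminated by the `record` column:
#   header   - tablet_id, session_index, start, duration_s (key/value)
#   target   - one row per target beat (index, hand, onset, window,
#              matched tap timestamp, accuracy, signed latency)
#   extra    - one row per unmatched tap (timestamp, drum, classification)
#   summary  - the eight session summary statistics (key/value)
#   metadata - session difficulty metadata (key/value)

OUTPUT_COLUMNS <- c("record", "key", "value", "target_index", "hand",
                    "onset_ms", "half_window_ms", "timestamp_ms",
                    "accuracy", "latency_ms", "classification")

SUMMARY_FIELDS <- c("mean_latency_ms", "mean_accuracy",
                    "mean_left_latency_ms", "mean_right_latency_ms",
                    "min_left_latency_ms", "min_right_latency_ms",
                    "mean_left_accuracy", "mean_right_accuracy")

METADATA_FIELDS <- c("total_targets", "window_duration_ms",
                     "success_threshold_pct")

fmt_num <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) sprintf("%.17g", v),
                              character(1)))
}

blank_row <- function(record, n = 1L) {
  row <- as.data.frame(stats::setNames(
    replicate(length(OUTPUT_COLUMNS), rep("", n), simplify = FALSE),
    OUTPUT_COLUMNS), stringsAsFactors = FALSE)
  row$record <- record
  row
}

#' Write a session result as the per-session output file
#'
#' Serialises a scored session together with its engagement header into
#' the comma-separated output format: a header block (tablet id, session,
#' start time, duration), one row per target beat and per extra tap, the
#' eight summary statistics, and the difficulty metadata block. No
#' personal identifiers are emitted; the only device reference is the
#' 16-character tablet code.
#'
#' @param result a `session_result` from [score_session()].
#' @param engagement a one-row [engagement_records()] table for this
#'   session.
#' @param path CSV file path.
#' @return Invisibly, `path`.
#' @export
write_output <- function(result, engagement, path) {
  stopifnot(inherits(result, "session_result"))
  if (nrow(engagement) != 1L) {
    stop("engagement must be a single record", call. = FALSE)
  }
  assert_tablet_id(engagement$tablet_id)
  hdr <- blank_row("header", 4L)
  hdr$key <- c("tablet_id", "session_index", "start", "duration_s")
  hdr$value <- c(engagement$tablet_id,
                 as.character(result$session_index),
                 engagement$start,
                 fmt_num(engagement$duration_s))
  r <- result$records
  tr <- blank_row("target", nrow(r))
  tr$target_index <- as.character(r$target_index)
  tr$hand <- r$hand
  tr$onset_ms <- fmt_num(r$onset_ms)
  tr$half_window_ms <- fmt_num(r$half_window_ms)
  tr$timestamp_ms <- fmt_num(r$tap_timestamp_ms)
  tr$accuracy <- as.character(r$accuracy)
  tr$latency_ms <- fmt_num(r$latency_ms)
  e <- result$extras
  ex <- blank_row("extra", nrow(e))
  if (nrow(e) > 0) {
    ex$hand <- e$drum
    ex$timestamp_ms <- fmt_num(e$timestamp_ms)
    ex$accuracy <- as.character(e$accuracy)
    ex$classification <- e$classification
  }
  sm <- blank_row("summary", length(SUMMARY_FIELDS))
  sm$key <- SUMMARY_FIELDS
  sm$value <- fmt_num(as.numeric(result$summary[1, SUMMARY_FIELDS]))
  md <- blank_row("metadata", length(METADATA_FIELDS))
  md$key <- METADATA_FIELDS
  md$value <- fmt_num(as.numeric(result$metadata[METADATA_FIELDS]))
  out <- rbind(hdr, tr, ex, sm, md)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

num_or_na <- function(x) ifelse(x == "", NA_real_, as.numeric(x))

#' Read a session output file back
#'
#' Parses the CSV written by [write_output()] and reconstructs the
#' `session_result` and its engagement record. Malformed files raise a
#' parse error naming the offending line.
#'
#' @param path CSV file path.
#' @return A list with elements `result` (a `session_result`) and
#'   `engagement` (a one-row [engagement_records()] table).
#' @export
read_output <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character"),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (!identical(names(df), OUTPUT_COLUMNS)) {
    stop(sprintf("'%s' line 1: expected columns %s", path,
                 paste(OUTPUT_COLUMNS, collapse = ",")), call. = FALSE)
  }
  line_no <- seq_len(nrow(df)) + 1L   # header is line 1
  bad <- which(!df$record %in% c("header", "target", "extra", "summary",
                                 "metadata"))
  if (length(bad) > 0) {
    stop(sprintf("'%s' line %d: unknown record type '%s'", path,
                 line_no[bad[1]], df$record[bad[1]]), call. = FALSE)
  }
  hdr <- df[df$record == "header", ]
  need_hdr <- c("tablet_id", "session_index", "start", "duration_s")
  if (!setequal(hdr$key, need_hdr)) {
    stop(sprintf("'%s': header block must carry %s", path,
                 paste(need_hdr, collapse = ",")), call. = FALSE)
  }
  h <- stats::setNames(hdr$value, hdr$key)
  engagement <- engagement_records(h[["tablet_id"]],
                                   as.integer(h[["session_index"]]),
                                   h[["start"]],
                                   as.numeric(h[["duration_s"]]))
  tr <- df[df$record == "target", ]
  records <- data.frame(
    target_index = as.integer(tr$target_index), hand = tr$hand,
    onset_ms = num_or_na(tr$onset_ms),
    half_window_ms = num_or_na(tr$half_window_ms),
    accuracy = as.integer(tr$accuracy),
    latency_ms = num_or_na(tr$latency_ms),
    tap_timestamp_ms = num_or_na(tr$timestamp_ms),
    stringsAsFactors = FALSE
  )
  ex <- df[df$record == "extra", ]
  extras <- data.frame(
    timestamp_ms = num_or_na(ex$timestamp_ms), drum = ex$hand,
    classification = ex$classification,
    accuracy = as.integer(ex$accuracy),
    stringsAsFactors = FALSE
  )
  sm <- df[df$record == "summary", ]
  if (!setequal(sm$key, SUMMARY_FIELDS)) {
    stop(sprintf("'%s': summary block must carry the %d statistics", path,
                 length(SUMMARY_FIELDS)), call. = FALSE)
  }
  summary <- as.data.frame(as.list(stats::setNames(
    num_or_na(sm$value), sm$key)))[SUMMARY_FIELDS]
  class(summary) <- c("session_summary", "data.frame")
  md <- df[df$record == "metadata", ]
  if (!setequal(md$key, METADATA_FIELDS)) {
    stop(sprintf("'%s': metadata block must carry %s", path,
                 paste(METADATA_FIELDS, collapse = ",")), call. = FALSE)
  }
  mdv <- stats::setNames(num_or_na(md$value), md$key)
  result <- structure(
    list(session_index = as.integer(h[["session_index"]]),
         records = records, extras = extras, summary = summary,
         metadata = list(
           total_targets = as.integer(mdv[["total_targets"]]),
           window_duration_ms = mdv[["window_duration_ms"]],
           success_threshold_pct = mdv[["success_threshold_pct"]])),
    class = "session_result"
  )
  list(result = result, engagement = engagement)
}
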