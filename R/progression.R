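#' Initial progression state
#'
#' At first launch the introduction and the first three training sessions
#' are available; everything else is locked. The unlocked set only ever
#' grows.
#'
#' @param catalog a `program_catalog`.
#' @return An object of class `progression_state`: list with `unlocked`
#'   (integer session indices, 0 = introduction), `best_accuracy`
#'   (named numeric, by session index), `history` (data.frame with
#'   columns `session_index`, `accuracy`, `timestamp`), and `threshold`.
#' @export
initial_state <- function(catalog = default_catalog()) {
  stopifnot(inherits(catalog, "program_catalog"))
  structure(
    list(unlocked = c(0L, 1L, 2L, 3L),
         best_accuracy = stats::setNames(numeric(0), character(0)),
         history = data.frame(session_index = integer(0),
                              accuracy = numeric(0),
                              timestamp = character(0),
                              stringsAsFactors = FALSE),
         threshold = catalog$unlock_threshold,
         max_session = max(vapply(training_sessions(catalog), `[[`, 0L,
                                  "index"))),
    class = "progression_state"
  )
}

#' @export
print.progression_state <- function(x, ...) {
  cat(sprintf("<progression_state> unlocked: %s\n",
              paste(sort(x$unlocked), collapse = ", ")))
  if (length(x$best_accuracy) > 0) {
    cat("  best accuracy:",
        paste(sprintf("s%s=%.0f%%", names(x$best_accuracy),
                      100 * x$best_accuracy), collapse = " "), "\n")
  }
  invisible(x)
}

#' Apply a session result to the progression state
#'
#' The gamification rule: from session 3 onward, reaching an accuracy of
#' at least the threshold (70% by default) unlocks the next, more
#' difficult session, and the end-of-session feedback reports
#' `unlocked_next`; otherwise the feedback is `completed`. Sessions 1 and
#' 2 always yield `completed` because their successors are unlocked from
#' the start. The comparison is `>=` on the exact fraction — 0.695 does
#' not round up. Replays can only improve `best_accuracy` and never
#' shrink the unlocked set.
#'
#' @param state a `progression_state`.
#' @param session_index the training session just played; must be
#'   unlocked.
#' @param accuracy session accuracy as a fraction in [0, 1].
#' @param timestamp optional ISO 8601 time of the play, recorded in the
#'   history.
#' @return A list with elements `state` (updated) and `feedback`
#'   (`"unlocked_next"` or `"completed"`).
#' @export
apply_result <- function(state, session_index, accuracy,
                         timestamp = NA_character_) {
  stopifnot(inherits(state, "progression_state"))
  session_index <- as.integer(session_index)
  if (!session_index %in% state$unlocked) {
    stop(sprintf("session %d is locked", session_index), call. = FALSE)
  }
  if (!is.numeric(accuracy) || length(accuracy) != 1L ||
      is.na(accuracy) || accuracy < 0 || accuracy > 1) {
    stop("accuracy must be a single value in [0, 1]", call. = FALSE)
  }
  state$history <- rbind(
    state$history,
    data.frame(session_index = session_index, accuracy = accuracy,
               timestamp = as.character(timestamp),
               stringsAsFactors = FALSE)
  )
  key <- as.character(session_index)
  state$best_accuracy[key] <- max(state$best_accuracy[key], accuracy,
                                  na.rm = TRUE)
  feedback <- "completed"
  if (session_index >= 3L && accuracy >= state$threshold) {
    nxt <- session_index + 1L
    if (nxt <= state$max_session) {
      if (!nxt %in% state$unlocked) {
        state$unlocked <- sort(c(state$unlocked, nxt))
      }
      feedback <- "unlocked_next"
    }
  }
  list(state = state, feedback = feedback)
}

#' Serialise / restore progression state as JSON
#'
#' @param state a `progression_state`.
#' @param path JSON file path.
#' @return `write_state` invisibly returns `path`; `read_state` returns
#'   the restored `progression_state`.
#' @export
write_state <- function(state, path) {
  stopifnot(inherits(state, "progression_state"))
  jsonlite::write_json(
    list(unlocked = state$unlocked,
         best_accuracy = as.list(state$best_accuracy),
         history = state$history,
         threshold = state$threshold,
         max_session = state$max_session),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  hist <- x$history
  if (is.null(hist) || length(hist) == 0) {
    hist <- data.frame(session_index = integer(0), accuracy = numeric(0),
                       timestamp = character(0), stringsAsFactors = FALSE)
  } else {
    hist <- as.data.frame(hist, stringsAsFactors = FALSE)
    hist$session_index <- as.integer(hist$session_index)
    hist$timestamp <- as.character(hist$timestamp)
  }
  ba <- unlist(x$best_accuracy)
  if (is.null(ba)) ba <- stats::setNames(numeric(0), character(0))
  structure(
    list(unlocked = sort(as.integer(x$unlocked)),
         best_accuracy = ba,
         history = hist,
         threshold = as.numeric(x$threshold),
         max_session = as.integer(x$max_session)),
    class = "progression_state"
  )
}
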