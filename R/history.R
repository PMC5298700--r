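#' Create an empty situation history
#'
#' The history is a transition log: one row per change of the current
#' situation set, strictly time-ordered. Replaying a trace therefore stores
#' at most one record per tick, and the per-tick situation sequence can be
#' reconstructed exactly from the transitions.
#'
#' @return A zero-row tibble of class `situation_history` with columns
#'   `timestamp`, `situations` (list of id sets) and `degree`.
#' @export
situation_history <- function() {
  out <- tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    situations = list(),
    degree = numeric()
  )
  class(out) <- c("situation_history", class(out))
  out
}

#' Record a situation transition
#'
#' Appends a record only when the situation id set differs from the last
#' stored one; an identical consecutive situation is skipped, keeping the
#' log a pure change history.
#'
#' @param history A [situation_history()].
#' @param timestamp Time of the inference (must be after the last record).
#' @param situations Character vector of current rule ids (may be empty —
#'   the transition to "no situation" is itself a change).
#' @param degree Degree of activation of the maximal rule(s); 0 when empty.
#' @return The history, with the record appended or unchanged.
#' @export
record_transition <- function(history, timestamp, situations, degree) {
  stopifnot(inherits(history, "situation_history"))
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  if (nrow(history) > 0 &&
      as.numeric(timestamp) <= as.numeric(history$timestamp[nrow(history)])) {
    rlang::abort("Out-of-order transition: timestamp must be after the last record.")
  }
  if (nrow(history) > 0 &&
      setequal(history$situations[[nrow(history)]], situations)) {
    return(history)
  }
  out <- dplyr::bind_rows(
    history,
    tibble::tibble(timestamp = timestamp,
                   situations = list(as.character(situations)),
                   degree = as.numeric(degree)))
  class(out) <- c("situation_history", setdiff(class(out), "situation_history"))
  out
}

#' Situation summary for a time window
#'
#' Returns exactly the transition records with `t0 <= timestamp <= t1`,
#' order preserved.
#'
#' @param history A [situation_history()].
#' @param t0,t1 Window bounds (`t0 <= t1`).
#' @return The filtered history tibble.
#' @export
get_situations_summary <- function(history, t0, t1) {
  stopifnot(inherits(history, "situation_history"))
  t0 <- as.POSIXct(t0, tz = "UTC"); t1 <- as.POSIXct(t1, tz = "UTC")
  if (as.numeric(t0) > as.numeric(t1)) rlang::abort("`t0` must not exceed `t1`.")
  history[as.numeric(history$timestamp) >= as.numeric(t0) &
            as.numeric(history$timestamp) <= as.numeric(t1), ]
}

#' Reconstruct the per-tick situation sequence from transitions
#'
#' @param history A [situation_history()].
#' @param times POSIXct vector of tick times.
#' @return List of id sets, one per tick (empty set before the first record).
#' @export
replay_situations <- function(history, times) {
  stopifnot(inherits(history, "situation_history"))
  times <- as.POSIXct(times, tz = "UTC")
  idx <- findInterval(as.numeric(times), as.numeric(history$timestamp))
  lapply(idx, function(i) if (i == 0) character() else history$situations[[i]])
}

#' Notification availability for the current situation
#'
#' Answers "may the client send this prompt now?". The verdict is
#' `"allowed"` only if every rule in the current argmax set allows the
#' notification type (a conservative conjunction over tied situations, to
#' keep prompting unobtrusive); `"denied"` if any denies it; and
#' `"unavailable"` when inference is suspended or no situation is currently
#' identified, in which case the client should fall back to fixed-time
#' prompting.
#'
#' @param type One of [notification_types()].
#' @param current Character vector of current rule ids (from
#'   [current_situation()]).
#' @param rules The [situation_rules()] store the ids refer to.
#' @param suspended Is inference currently suspended?
#' @return A one-row tibble `notification_type`, `verdict`.
#' @export
check_status <- function(type, current, rules, suspended = FALSE) {
  type <- rlang::arg_match(type, notification_types())
  stopifnot(inherits(rules, "situation_rules"))
  verdict <- if (suspended || length(current) == 0) {
    "unavailable"
  } else {
    if (!all(current %in% rules$id)) {
      rlang::abort("`current` contains ids not present in `rules`.")
    }
    allows <- purrr::map_lgl(current, function(id) {
      rules$availability[[which(rules$id == id)]][[type]]
    })
    if (all(allows)) "allowed" else "denied"
  }
  tibble::tibble(notification_type = type, verdict = verdict)
}

#' Write / read a situation history as JSONL
#'
#' One JSON object per line (`timestamp`, `situations`, `degree`): an
#' append-only, diff-able on-disk log.
#'
#' @param history A [situation_history()].
#' @param path File path.
#' @return `path` invisibly (write); a [situation_history()] (read).
#' @export
write_history_jsonl <- function(history, path) {
  stopifnot(inherits(history, "situation_history"))
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(history))) {
    writeLines(jsonlite::toJSON(list(
      timestamp = format(history$timestamp[i], "%Y-%m-%dT%H:%M:%S",
                         tz = "UTC"),
      situations = history$situations[[i]],
      degree = history$degree[i]
    ), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_history_jsonl
#' @export
read_history_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- situation_history()
  for (l in lines) {
    rec <- jsonlite::fromJSON(l)
    out <- record_transition(
      out, as.POSIXct(rec$timestamp, tz = "UTC",
                      format = "%Y-%m-%dT%H:%M:%S"),
      as.character(rec$situations), rec$degree)
  }
  out
}

#' Export a situation summary as CSV or JSON
#'
#' @param history A [situation_history()] (or a windowed summary of one).
#' @param path Destination ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
export_summary <- function(history, path) {
  stopifnot(inherits(history, "situation_history"))
  flat <- tibble::tibble(
    timestamp = format(history$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    situations = purrr::map_chr(history$situations, paste, collapse = ";"),
    degree = history$degree
  )
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(flat, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  } else {
    readr::write_csv(flat, path, progress = FALSE)
  }
  invisible(path)
}
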