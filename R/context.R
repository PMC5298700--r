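#' Preprocess raw context observations into snapshots
#'
#' Adjusts raw sensor records into the engine's input format: the timestamp
#' is truncated to minute resolution (seconds carry no information at the
#' fuzzy sets' granularity) and converted to the day-of-week and time-of-day
#' coordinates; altitude is dropped; the 0-100 activity-recognition
#' probabilities are normalised to `[0, 1]`; and the age of the location fix
#' is computed so stale fixes can be down-weighted during inference.
#'
#' Expected raw columns: `timestamp`, `lat`, `lon`, optional `alt`, optional
#' `fix_time`, `battery`, and `p_<class>` for the seven activity classes
#' (values 0-100). A missing position (`NA` lat/lon) yields a snapshot with
#' an absent position — inference on it is suspended, not zeroed.
#'
#' @param raw Data frame of raw observations.
#' @param malformed `"strict"` (error, reporting the offending row) or
#'   `"skip"` (drop malformed rows with a message).
#' @return A snapshot tibble: `timestamp`, `x_w`, `x_t`, `lat`, `lon`,
#'   `fix_age` (seconds), `battery`, `a_<class>` (normalised probabilities).
#' @examples
#' raw <- tibble::tibble(
#'   timestamp = "2017-01-11 10:15:42", lat = 52.0, lon = 4.3, alt = 812,
#'   fix_time = "2017-01-11 10:15:00", battery = 0.8,
#'   p_in_vehicle = 0, p_on_bicycle = 0, p_on_foot = 0, p_running = 0,
#'   p_still = 60, p_tilting = 0, p_walking = 30)
#' preprocess(raw)
#' @export
preprocess <- function(raw, malformed = c("strict", "skip")) {
  malformed <- rlang::arg_match(malformed)
  raw <- tibble::as_tibble(raw)
  classes <- fuzzy_vocabulary()$activity_classes
  pcols <- paste0("p_", classes)
  required <- c("timestamp", "lat", "lon", "battery", pcols)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("Raw trace is missing columns:",
                       paste(missing_cols, collapse = ", ")))
  }

  parse_ts <- function(x) {
    if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
    as.POSIXct(as.character(x), tz = "UTC",
               tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                              "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"),
               optional = TRUE)
  }
  ts <- parse_ts(raw$timestamp)
  probs_ok <- Reduce(`&`, lapply(raw[pcols], function(p)
    is.na(p) | (p >= 0 & p <= 100)))
  battery_ok <- is.na(raw$battery) | (raw$battery >= 0 & raw$battery <= 1)
  bad <- is.na(ts) | !probs_ok | !battery_ok
  if (any(bad)) {
    lines <- which(bad)
    msg <- sprintf("%d malformed observation(s) at row(s) %s.",
                   length(lines),
                   paste(utils::head(lines, 5), collapse = ", "))
    if (malformed == "strict") rlang::abort(msg) else message(msg, " Skipped.")
    raw <- raw[!bad, ]
    ts <- ts[!bad]
  }

  ts_min <- trunc_minute(ts)
  fix_age <- if ("fix_time" %in% names(raw)) {
    ft <- parse_ts(raw$fix_time)
    age <- as.numeric(ts, units = "secs") - as.numeric(ft, units = "secs")
    dplyr::coalesce(pmax(age, 0), 0)
  } else {
    rep(0, nrow(raw))
  }

  out <- tibble::tibble(
    timestamp = ts_min,
    x_w = day_week_value(ts_min),
    x_t = time_of_day_value(ts_min),
    lat = as.numeric(raw$lat),
    lon = as.numeric(raw$lon),
    fix_age = fix_age,
    battery = as.numeric(raw$battery)
  )
  for (cls in classes) {
    out[[paste0("a_", cls)]] <- as.numeric(raw[[paste0("p_", cls)]]) / 100
  }
  out
}

trunc_minute <- function(ts) {
  as.POSIXct(floor(as.numeric(ts) / 60) * 60,
             origin = "1970-01-01", tz = "UTC")
}

#' Confidence in a location fix of a given age
#'
#' Location can become temporarily unavailable (no satellite view, poor
#' network coverage), so inference must trust old fixes less. Confidence
#' decays linearly from 1 at age zero to 0 at the horizon; it multiplies the
#' location condition truth, so stale fixes lower the degree of activation.
#'
#' @param fix_age Seconds since the fix (non-negative).
#' @param horizon Seconds to full decay; defaults to 27 minutes, the point at
#'   which the engine declares inference unavailable altogether.
#' @return Confidence values in `[0, 1]`.
#' @examples
#' location_confidence(c(0, 810, 1620))
#' @export
location_confidence <- function(fix_age, horizon = 27 * 60) {
  if (!is.numeric(fix_age) || any(is.na(fix_age))) {
    rlang::abort("`fix_age` must be numeric and non-missing.")
  }
  if (any(fix_age < 0)) rlang::abort("`fix_age` must be non-negative.")
  if (!is.numeric(horizon) || horizon <= 0) {
    rlang::abort("`horizon` must be a positive number of seconds.")
  }
  pmax(0, 1 - fix_age / horizon)
}

#' Read a context trace from CSV or JSONL
#'
#' The on-disk trace format has one observation per line with the header
#' `timestamp, lat, lon, alt, fix_time, battery, p_in_vehicle, ...,
#' p_walking`. JSONL holds one observation object per line with the same
#' fields.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"jsonl"`.
#' @return A raw-observation tibble (not yet preprocessed).
#' @export
read_context_trace <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- rlang::arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  if (format == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    purrr::map_dfr(lines, function(l) {
      tibble::as_tibble(jsonlite::fromJSON(l))
    })
  }
}

#' Write a context trace to CSV or JSONL
#'
#' @param trace Raw-observation tibble.
#' @param path Destination path.
#' @inheritParams read_context_trace
#' @return `path`, invisibly.
#' @export
write_context_trace <- function(trace, path, format = c("auto", "csv", "jsonl")) {
  format <- rlang::arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  if (format == "csv") {
    readr::write_csv(trace, path, progress = FALSE)
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    for (i in seq_len(nrow(trace))) {
      writeLines(jsonlite::toJSON(as.list(trace[i, ]), auto_unbox = TRUE,
                                  digits = NA, null = "null", na = "null"),
                 con)
    }
  }
  invisible(path)
}
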