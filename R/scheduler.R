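#' Battery-dependent inference interval
#'
#' To balance recognition latency against energy drain, inference runs every
#' 3, 6 or 9 minutes depending on the battery level: 3 min on a high battery,
#' 6 min mid, 9 min low. Tier boundaries are configurable; defaults put the
#' high tier above 50% and the low tier at or below 20%.
#'
#' @param battery Battery fraction(s) in `[0, 1]`.
#' @param cutoffs Named vector `c(low = ..., high = ...)` of tier boundaries.
#' @return Interval(s) in minutes, each one of 3, 6 or 9.
#' @examples
#' inference_interval(c(0.9, 0.4, 0.05))
#' @export
inference_interval <- function(battery, cutoffs = c(low = 0.2, high = 0.5)) {
  tier <- battery_tier(battery, cutoffs)
  c(high = 3, mid = 6, low = 9)[tier]
}

#' Battery-dependent sensor warm-up delay
#'
#' Location and activity services must be activated some time before data
#' retrieval for the readings to be accurate: 35 s on a high battery (the
#' minimum considered safe for fresh activity data), 45 s mid, 60 s low.
#'
#' @inheritParams inference_interval
#' @return Warm-up delay(s) in seconds, each one of 35, 45 or 60.
#' @export
warmup_delay <- function(battery, cutoffs = c(low = 0.2, high = 0.5)) {
  tier <- battery_tier(battery, cutoffs)
  c(high = 35, mid = 45, low = 60)[tier]
}

battery_tier <- function(battery, cutoffs = c(low = 0.2, high = 0.5)) {
  if (!is.numeric(battery) || any(is.na(battery)) ||
      any(battery < 0 | battery > 1)) {
    rlang::abort("`battery` must lie in [0, 1].")
  }
  stopifnot(all(c("low", "high") %in% names(cutoffs)),
            cutoffs["low"] < cutoffs["high"])
  dplyr::case_when(
    battery > cutoffs[["high"]] ~ "high",
    battery >= cutoffs[["low"]] ~ "mid",
    TRUE ~ "low"
  )
}

#' Scheduler configuration
#'
#' @param tier_cutoffs Battery tier boundaries, `c(low = ..., high = ...)`.
#' @param decay_horizon Seconds over which location confidence decays
#'   ([location_confidence()]).
#' @param stale_cutoff_min Minutes of continuous context-data unavailability
#'   after which inference is declared stopped; fixed by design at three
#'   times the largest inference interval (3 x 9 = 27 min).
#' @return A named list of class `loop_config`.
#' @export
loop_config <- function(tier_cutoffs = c(low = 0.2, high = 0.5),
                        decay_horizon = 27 * 60,
                        stale_cutoff_min = 27) {
  structure(list(tier_cutoffs = tier_cutoffs, decay_horizon = decay_horizon,
                 stale_cutoff_min = stale_cutoff_min),
            class = "loop_config")
}

#' Run the simulated energy-aware inference loop
#'
#' Replays a raw context trace under a simulated clock. At each tick the
#' latest observation at or before the tick time is preprocessed and the
#' rules evaluated; the next tick is scheduled `inference_interval(battery)`
#' minutes later, and the sensor warm-up lead for the tick is recorded.
#' Ticks whose observation lacks location or activity data suspend inference;
#' once suspension has lasted `stale_cutoff_min` minutes an `unavailable`
#' event is emitted for the EMA client, and the first successful inference
#' thereafter emits `available`. Changes of the current (argmax) situation
#' set are appended to the transition history.
#'
#' The loop is event-driven and fully deterministic given the trace, rules
#' and config: no wall clock is consulted.
#'
#' @param trace Raw-observation tibble, sorted by timestamp.
#' @param rules A [situation_rules()] store (may be empty: the loop runs and
#'   records nothing).
#' @param config A [loop_config()].
#' @return An object of class `situfuzz_loop`: a list with
#'   * `ticks` — one row per tick (`time`, `battery`, `interval_min`,
#'     `warmup_s`, `suspended`, `situations` list-column, `degree`),
#'   * `events` — availability events (`time`, `event`,
#'     `elapsed_min` since suspension began for `unavailable` events),
#'   * `history` — the transition log (a [situation_history()]).
#' @export
run_inference_loop <- function(trace, rules, config = loop_config()) {
  stopifnot(inherits(config, "loop_config"))
  trace <- tibble::as_tibble(trace)
  if (nrow(trace) == 0) rlang::abort("`trace` is empty.")
  ts <- as_clock_time(trace$timestamp)
  ts <- as.POSIXct(ts, tz = "UTC")
  if (is.unsorted(as.numeric(ts))) {
    rlang::abort("`trace` must be sorted by timestamp.")
  }
  snaps <- preprocess(trace, malformed = "strict")

  t0 <- snaps$timestamp[1]
  t_end <- snaps$timestamp[nrow(snaps)]
  t <- t0
  suspension_start <- NULL
  unavailable_emitted <- FALSE
  history <- situation_history()
  prev_set <- NULL

  ticks <- list()
  events <- list()
  snap_times <- as.numeric(snaps$timestamp)

  while (as.numeric(t) <= as.numeric(t_end)) {
    i <- findInterval(as.numeric(t), snap_times)
    snap <- snaps[i, ]
    battery <- snap$battery
    interval <- inference_interval(battery, config$tier_cutoffs)
    warmup <- warmup_delay(battery, config$tier_cutoffs)
    # age the fix relative to the simulated clock, not the observation time
    snap$fix_age <- snap$fix_age + as.numeric(t) - as.numeric(snap$timestamp)

    usable <- !is.na(snap$lat) && !is.na(snap$lon) &&
      !anyNA(snap[paste0("a_", fuzzy_vocabulary()$activity_classes)])

    if (usable) {
      act <- tryCatch(
        evaluate_rules(snap, rules, decay_horizon = config$decay_horizon),
        situfuzz_suspended = function(e) NULL)
    } else {
      act <- NULL
    }

    if (is.null(act)) {
      if (is.null(suspension_start)) suspension_start <- t
      elapsed_min <- (as.numeric(t) - as.numeric(suspension_start)) / 60
      if (!unavailable_emitted && elapsed_min >= config$stale_cutoff_min) {
        events[[length(events) + 1]] <- tibble::tibble(
          time = t, event = "unavailable", elapsed_min = elapsed_min)
        unavailable_emitted <- TRUE
      }
      cur <- list(ids = character(), degree = NA_real_, suspended = TRUE)
    } else {
      if (unavailable_emitted) {
        events[[length(events) + 1]] <- tibble::tibble(
          time = t, event = "available", elapsed_min = NA_real_)
        unavailable_emitted <- FALSE
      }
      suspension_start <- NULL
      pos <- act[act$degree > 0, ]
      if (nrow(pos) > 0) {
        top <- max(pos$degree)
        ids <- sort(pos$rule_id[pos$degree >= top - ARGMAX_TOL])
      } else {
        top <- 0
        ids <- character()
      }
      cur <- list(ids = ids, degree = if (length(ids)) top else 0,
                  suspended = FALSE)
      if (is.null(prev_set) || !setequal(prev_set, ids)) {
        history <- record_transition(history, t, ids,
                                     if (length(ids)) top else 0)
        prev_set <- ids
      }
    }

    ticks[[length(ticks) + 1]] <- tibble::tibble(
      time = t, battery = battery, interval_min = interval,
      warmup_s = warmup, suspended = cur$suspended,
      situations = list(cur$ids), degree = cur$degree)

    t <- t + interval * 60
  }

  structure(
    list(
      ticks = dplyr::bind_rows(ticks),
      events = if (length(events)) dplyr::bind_rows(events) else
        tibble::tibble(time = as.POSIXct(character(), tz = "UTC"),
                       event = character(), elapsed_min = numeric()),
      history = history
    ),
    class = "situfuzz_loop"
  )
}

#' @export
print.situfuzz_loop <- function(x, ...) {
  cat(sprintf(
    "<situfuzz_loop> %d ticks, %d availability event(s), %d transition(s)\n",
    nrow(x$ticks), nrow(x$events), nrow(x$history)))
  invisible(x)
}

#' EMA-client prompting mode implied by availability events
#'
#' A reference stub for the client side of the availability contract: the
#' assessment client prompts situation-aware while inference is available
#' and falls back to fixed-time prompting after an `unavailable` event,
#' switching back on `available`. This models the client's dynamic
#' reconfiguration; it is not an assessment application.
#'
#' @param loop A [run_inference_loop()] result.
#' @return Tibble `time`, `mode` (`"situation_aware"` / `"fixed_time"`),
#'   starting in situation-aware mode at the first tick.
#' @export
ema_client_modes <- function(loop) {
  stopifnot(inherits(loop, "situfuzz_loop"))
  out <- tibble::tibble(time = loop$ticks$time[1], mode = "situation_aware")
  if (nrow(loop$events) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      time = loop$events$time,
      mode = ifelse(loop$events$event == "unavailable",
                    "fixed_time", "situation_aware")))
  }
  out
}
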