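#' Define a synthetic daily-routine scenario
#'
#' A scenario is a set of named places and a time-ordered, non-overlapping
#' episode schedule. Each episode pins the agent to a place with a mixture
#' of activity classes and (optionally) the situation label that a correct
#' engine should infer there; unlabelled episodes (sleep outside the night
#' window, idle time at home) carry `NA`. During gaps between episodes at
#' different places the agent transits along the straight path between them.
#'
#' @param places Tibble with columns `place`, `lat`, `lon`.
#' @param episodes Tibble with columns `start`, `end` (POSIXct), `place`,
#'   `activities` (list-column of activity classes), `situation` (label or
#'   `NA`).
#' @param gps_sigma Isotropic GPS noise standard deviation in metres
#'   (per axis); default 10 m, a typical open-sky smartphone fix.
#' @param activity_concentration Total probability mass placed on the
#'   episode's activity classes before noise; default 0.95.
#' @param activity_noise_sd Gaussian noise s.d. added to each class
#'   probability (on the 0-1 scale); default 0.03.
#' @param battery_discharge_per_hour Linear battery drain per hour; default
#'   0.04 (4%/h), with an instantaneous overnight recharge at midnight so
#'   every battery tier is exercised daily.
#' @return An object of class `routine_scenario`.
#' @export
routine_scenario <- function(places, episodes, gps_sigma = 10,
                             activity_concentration = 0.95,
                             activity_noise_sd = 0.03,
                             battery_discharge_per_hour = 0.04) {
  places <- tibble::as_tibble(places)
  episodes <- tibble::as_tibble(episodes)
  stopifnot(all(c("place", "lat", "lon") %in% names(places)),
            all(c("start", "end", "place", "activities", "situation") %in%
                  names(episodes)),
            gps_sigma >= 0, activity_concentration > 0,
            activity_noise_sd >= 0, battery_discharge_per_hour >= 0)
  if (!all(episodes$place %in% places$place)) {
    rlang::abort("Episode places must be defined in `places`.")
  }
  episodes <- dplyr::arrange(episodes, .data$start)
  s <- as.numeric(episodes$start); e <- as.numeric(episodes$end)
  if (any(e <= s)) rlang::abort("Episodes must have `end` after `start`.")
  if (nrow(episodes) > 1 && any(s[-1] < e[-nrow(episodes)])) {
    rlang::abort("Episodes must not overlap.")
  }
  structure(
    list(places = places, episodes = episodes, gps_sigma = gps_sigma,
         activity_concentration = activity_concentration,
         activity_noise_sd = activity_noise_sd,
         battery_discharge_per_hour = battery_discharge_per_hour),
    class = "routine_scenario")
}

#' @export
print.routine_scenario <- function(x, ...) {
  cat(sprintf(
    "<routine_scenario> %d places, %d episodes, gps sigma %g m\n",
    nrow(x$places), nrow(x$episodes), x$gps_sigma))
  invisible(x)
}

# metres offset -> degrees at a given latitude (small-displacement approx)
metres_to_deg <- function(north_m, east_m, lat) {
  list(dlat = north_m / 111320,
       dlon = east_m / (111320 * cos(lat * pi / 180)))
}

#' Simulate a labelled context trace from a routine scenario
#'
#' Produces one raw observation per minute across the episode schedule:
#' position is the scheduled place (or the linear transit path between
#' places during gaps) plus isotropic Gaussian GPS noise; activity
#' probabilities (0-100 scale) concentrate the configured mass on the
#' episode's classes, split evenly, with Gaussian noise; transit minutes are
#' walking; battery discharges linearly through each day from a full
#' overnight charge. The ground-truth label of a minute is its episode's
#' situation (`NA` in gaps and unlabelled episodes) — labels depend only on
#' the schedule, never on the noise.
#'
#' @param scenario A [routine_scenario()].
#' @param seed Integer seed; the trace is byte-identical for equal seeds.
#' @return A list of class `situfuzz_sim`: `trace` (raw-observation tibble
#'   ready for [preprocess()] or [run_inference_loop()]) and `labels`
#'   (tibble `timestamp`, `situation`).
#' @export
simulate_routine <- function(scenario, seed = 1L) {
  stopifnot(inherits(scenario, "routine_scenario"))
  withr::with_seed(as.integer(seed), simulate_routine_impl(scenario))
}

simulate_routine_impl <- function(scenario) {
  ep <- scenario$episodes
  places <- scenario$places
  classes <- fuzzy_vocabulary()$activity_classes
  t0 <- min(ep$start); t1 <- max(ep$end)
  times <- seq(from = t0, to = t1 - 60, by = 60)
  n <- length(times)
  tn <- as.numeric(times)

  place_xy <- function(p) {
    i <- match(p, places$place)
    c(places$lat[i], places$lon[i])
  }
  ep_start <- as.numeric(ep$start); ep_end <- as.numeric(ep$end)

  lat <- numeric(n); lon <- numeric(n)
  label <- rep(NA_character_, n)
  act_sets <- vector("list", n)
  idx <- findInterval(tn, ep_start)
  for (k in seq_len(n)) {
    i <- idx[k]
    if (i >= 1 && tn[k] < ep_end[i]) {
      xy <- place_xy(ep$place[i])
      lat[k] <- xy[1]; lon[k] <- xy[2]
      label[k] <- ep$situation[i]
      act_sets[[k]] <- ep$activities[[i]]
    } else {
      # gap: transit between the previous and next episode's places
      from <- place_xy(ep$place[max(i, 1)])
      to <- place_xy(ep$place[min(i + 1, nrow(ep))])
      g0 <- if (i >= 1) ep_end[i] else tn[k]
      g1 <- if (i + 1 <= nrow(ep)) ep_start[i + 1] else tn[k]
      frac <- if (g1 > g0) (tn[k] - g0) / (g1 - g0) else 0
      lat[k] <- from[1] + frac * (to[1] - from[1])
      lon[k] <- from[2] + frac * (to[2] - from[2])
      act_sets[[k]] <- "walking"
    }
  }

  off <- metres_to_deg(stats::rnorm(n, 0, scenario$gps_sigma),
                       stats::rnorm(n, 0, scenario$gps_sigma), mean(lat))
  lat <- lat + off$dlat
  lon <- lon + off$dlon

  probs <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (k in seq_len(n)) {
    sel <- act_sets[[k]]
    probs[k, sel] <- scenario$activity_concentration / length(sel)
  }
  if (scenario$activity_noise_sd > 0) {
    probs <- probs + stats::rnorm(length(probs), 0, scenario$activity_noise_sd)
  }
  probs <- pmin(pmax(probs, 0), 1) * 100

  lt <- as.POSIXlt(times, tz = "UTC")
  hours_of_day <- lt$hour + lt$min / 60
  battery <- pmin(pmax(1 - scenario$battery_discharge_per_hour * hours_of_day,
                       0.05), 1)

  trace <- tibble::tibble(
    timestamp = times, lat = lat, lon = lon, alt = 0,
    fix_time = times, battery = battery)
  for (cls in classes) trace[[paste0("p_", cls)]] <- probs[, cls]

  structure(
    list(trace = trace,
         labels = tibble::tibble(timestamp = times, situation = label)),
    class = "situfuzz_sim")
}

#' @export
print.situfuzz_sim <- function(x, ...) {
  cat(sprintf("<situfuzz_sim> %d minutes, %d labelled\n",
              nrow(x$trace), sum(!is.na(x$labels$situation))))
  invisible(x)
}

#' A week of a synthetic agent's routine
#'
#' The stock scenario used throughout the package's examples and
#' self-checks: seven days (starting on a Sunday) of an agent who sleeps at
#' home, works 09:00-17:00 on weekdays three kilometres away, exercises in a
#' park, and runs a Saturday supermarket errand. All anchor points are at
#' least two kilometres apart, so situations are geographically
#' well-separated. [default_rules()] returns the four matching situation
#' definitions.
#'
#' @param days Number of days to schedule (default 7).
#' @param start First day, a date-like string or POSIXct (default
#'   `"2017-01-01"`, a Sunday).
#' @param ... Passed to [routine_scenario()] (e.g. `gps_sigma`).
#' @return A [routine_scenario()].
#' @export
default_scenario <- function(days = 7, start = "2017-01-01", ...) {
  start <- as.POSIXct(paste(as.character(start), "00:00:00"), tz = "UTC")
  places <- tibble::tibble(
    place = c("home", "work", "park", "supermarket"),
    lat = c(52.0000, 52.0000, 52.0225, 52.0000),
    lon = c(4.3000, 4.3438, 4.3000, 4.2708))

  day_episodes <- function(day_start, dow) {
    h <- function(x) day_start + x * 3600
    base <- list(
      list(h(0), h(3), "home", list("still"), "home_rest"),
      list(h(19), h(24), "home", list("still"), "home_rest"))
    mid <- if (dow %in% 1:5) {
      list(
        list(h(3), h(8 + 50 / 60), "home", list("still"), NA),
        list(h(9), h(17), "work", list(c("still", "walking")), "working"),
        list(h(17 + 10 / 60), h(18 + 10 / 60), "park",
             list(c("walking", "running")), "exercise"),
        list(h(18 + 20 / 60), h(19), "home", list("still"), NA))
    } else if (dow == 6) {
      list(
        list(h(3), h(14 + 50 / 60), "home", list("still"), NA),
        list(h(15), h(16), "supermarket", list("walking"), "errand"),
        list(h(16 + 10 / 60), h(19), "home", list("still"), NA))
    } else {
      list(
        list(h(3), h(14 + 50 / 60), "home", list("still"), NA),
        list(h(15), h(17), "park", list(c("walking", "running")), "exercise"),
        list(h(17 + 10 / 60), h(19), "home", list("still"), NA))
    }
    purrr::map_dfr(c(base[1], mid, base[2]), function(e) {
      tibble::tibble(start = e[[1]], end = e[[2]], place = e[[3]],
                     activities = e[[4]], situation = e[[5]])
    })
  }

  episodes <- purrr::map_dfr(seq_len(days) - 1, function(d) {
    day_start <- start + d * 86400
    dow <- as.POSIXlt(day_start, tz = "UTC")$wday
    day_episodes(day_start, dow)
  })
  routine_scenario(places, episodes, ...)
}

#' Situation rules matching [default_scenario()]
#'
#' Four situations over the scenario's anchor points: resting at home at
#' night, working on weekday mornings/afternoons, exercising in the park,
#' and the weekend supermarket errand. The working situation denies
#' sleep-quality prompts; the others allow all six notification types.
#'
#' @return A [situation_rules()] store with four rules.
#' @export
default_rules <- function() {
  store <- situation_rules()
  store <- add_situation(store, situation_rule(
    "home_rest", lat = 52.0000, lon = 4.3000, location_term = "same_place",
    day_terms = c("weekday", "weekend"), time_terms = "night",
    activities = "still"))
  store <- add_situation(store, situation_rule(
    "working", lat = 52.0000, lon = 4.3438, location_term = "near",
    day_terms = "weekday", time_terms = c("morning", "afternoon"),
    activities = c("still", "walking"),
    availability = c(sleep_quality = FALSE)))
  store <- add_situation(store, situation_rule(
    "exercise", lat = 52.0225, lon = 4.3000, location_term = "near",
    day_terms = c("weekday", "weekend"),
    time_terms = c("afternoon", "night"),
    activities = c("walking", "running")))
  store <- add_situation(store, situation_rule(
    "errand", lat = 52.0000, lon = 4.2708, location_term = "near",
    day_terms = "weekend", time_terms = "afternoon",
    activities = "walking"))
  store
}

#' Score engine inferences against ground-truth labels
#'
#' Evaluates the rules at every minute of a labelled trace and compares the
#' current (argmax) situation set with the label. A tick counts as correct
#' when some rule fires and the label is among the argmax ids, and as
#' incorrect when some rule fires but the label is not (including fires
#' during unlabelled minutes — false positives). The headline percentage,
#' `100 * correct / (correct + incorrect)`, covers only ticks where a
#' situation was identified, mirroring a confirmation protocol in which
#' only displayed situations can be judged; ticks where nothing fires are
#' tallied separately as `correct_negative` (no label) or `missed`
#' (labelled but silent).
#'
#' @param trace Raw-observation tibble (e.g. from [simulate_routine()]).
#' @param labels Tibble `timestamp`, `situation` aligned to the trace.
#' @param rules A [situation_rules()] store.
#' @param decay_horizon Passed to [evaluate_rules()].
#' @return An object of class `situfuzz_accuracy`: list with `overall`
#'   (one-row tibble of counts and `percent`), `by_situation` (per-label
#'   breakdown over fired ticks) and `ticks` (per-tick detail).
#' @export
evaluate_accuracy <- function(trace, labels, rules, decay_horizon = 27 * 60) {
  trace <- tibble::as_tibble(trace)
  labels <- tibble::as_tibble(labels)
  if (nrow(trace) == 0) rlang::abort("`trace` is empty.")
  if (nrow(trace) != nrow(labels)) {
    rlang::abort("`trace` and `labels` must have the same number of ticks.")
  }
  snaps <- preprocess(trace, malformed = "strict")
  act <- evaluate_rules(snaps, rules, decay_horizon = decay_horizon)

  top <- act |>
    dplyr::group_by(.data$timestamp) |>
    dplyr::summarise(
      ids = list(sort(.data$rule_id[.data$degree > 0 &
                                      .data$degree >= max(.data$degree) -
                                      ARGMAX_TOL])),
      degree = max(.data$degree),
      .groups = "drop")

  ticks <- tibble::tibble(timestamp = snaps$timestamp,
                          label = labels$situation) |>
    dplyr::left_join(top, by = "timestamp")
  if (nrow(rules) == 0) {
    ticks$degree <- 0
    ticks$ids <- rep(list(character()), nrow(ticks))
  }
  ticks <- ticks |>
    dplyr::mutate(
      fired = purrr::map_int(.data$ids, length) > 0,
      hit = purrr::map2_lgl(.data$label, .data$ids,
                            ~ !is.na(.x) && .x %in% .y),
      outcome = dplyr::case_when(
        .data$fired & .data$hit ~ "correct",
        .data$fired & !.data$hit ~ "incorrect",
        !.data$fired & is.na(.data$label) ~ "correct_negative",
        TRUE ~ "missed"))

  counts <- table(factor(ticks$outcome,
                         levels = c("correct", "incorrect",
                                    "correct_negative", "missed")))
  n_c <- counts[["correct"]]; n_i <- counts[["incorrect"]]
  overall <- tibble::tibble(
    ticks = nrow(ticks), correct = n_c, incorrect = n_i,
    correct_negative = counts[["correct_negative"]],
    missed = counts[["missed"]],
    percent = if (n_c + n_i > 0) 100 * n_c / (n_c + n_i) else NA_real_)

  by_situation <- ticks |>
    dplyr::filter(.data$fired, !is.na(.data$label)) |>
    dplyr::group_by(situation = .data$label) |>
    dplyr::summarise(
      correct = sum(.data$hit), incorrect = sum(!.data$hit),
      percent = 100 * mean(.data$hit), .groups = "drop")

  structure(list(overall = overall, by_situation = by_situation,
                 ticks = ticks),
            class = "situfuzz_accuracy")
}

#' @export
print.situfuzz_accuracy <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<situfuzz_accuracy> %d ticks: %d correct, %d incorrect among fired (%.2f%%); %d correct-negative, %d missed\n",
    o$ticks, o$correct, o$incorrect, o$percent, o$correct_negative, o$missed))
  invisible(x)
}

#' Analyze yes/no confirmation logs
#'
#' Computes the per-participant and overall success percentages from user
#' confirmations of displayed situations: each participant's percentage is
#' `100 * correct / (correct + incorrect)`, and the overall percentage pools
#' the summed counts (not the mean of percentages).
#'
#' @param data Either per-confirmation records with columns `participant`
#'   and `answer` (`"yes"`/`"no"`), or a pre-aggregated counts table with
#'   columns `participant`, `correct`, `incorrect`.
#' @return An object of class `situfuzz_confirmations`: list with
#'   `by_participant` (tibble `participant`, `correct`, `incorrect`,
#'   `total`, `percent`) and `overall` (one-row tibble).
#' @examples
#' analyze_confirmations(example_confirmation_counts())
#' @export
analyze_confirmations <- function(data) {
  data <- tibble::as_tibble(data)
  if (all(c("correct", "incorrect") %in% names(data))) {
    counts <- dplyr::transmute(
      data, participant = .data$participant,
      correct = as.integer(.data$correct),
      incorrect = as.integer(.data$incorrect))
  } else if (all(c("participant", "answer") %in% names(data))) {
    if (!all(data$answer %in% c("yes", "no"))) {
      rlang::abort('`answer` must be "yes" or "no".')
    }
    counts <- data |>
      dplyr::group_by(participant = .data$participant) |>
      dplyr::summarise(correct = sum(.data$answer == "yes"),
                       incorrect = sum(.data$answer == "no"),
                       .groups = "drop")
  } else {
    rlang::abort(
      "`data` needs either (participant, answer) records or (participant, correct, incorrect) counts.")
  }
  counts <- dplyr::mutate(counts, total = .data$correct + .data$incorrect)
  if (any(counts$total == 0)) {
    rlang::abort("Every participant must have at least one confirmation.")
  }
  by_participant <- dplyr::mutate(
    counts, percent = 100 * .data$correct / .data$total)
  overall <- tibble::tibble(
    participants = nrow(counts),
    correct = sum(counts$correct),
    incorrect = sum(counts$incorrect),
    total = sum(counts$total),
    percent = 100 * sum(counts$correct) / sum(counts$total))
  structure(list(by_participant = by_participant, overall = overall),
            class = "situfuzz_confirmations")
}

#' @export
print.situfuzz_confirmations <- function(x, ...) {
  o <- x$overall
  cat(sprintf(
    "<situfuzz_confirmations> %d participants, %d confirmations: %d correct, %d incorrect (%.2f%%)\n",
    o$participants, o$total, o$correct, o$incorrect, round(o$percent, 2)))
  invisible(x)
}

#' Confirmation counts from a 12-participant field evaluation
#'
#' Per-participant counts of situations confirmed correct and incorrect
#' during a seven-day field evaluation of the inference engine, with the
#' number of situations each participant defined. Bundled as package data
#' for the worked accuracy-arithmetic example.
#'
#' @return Tibble `participant`, `defined`, `correct`, `incorrect`.
#' @export
example_confirmation_counts <- function() {
  path <- system.file("extdata", "confirmation_counts.csv",
                      package = "situfuzz", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Display form of a degree of activation
#'
#' Rounds a degree in `[0, 1]` to the whole-percent figure a confirmation
#' prompt shows the user.
#'
#' @param degree Numeric degree(s) in `[0, 1]`.
#' @return Integer percent(s).
#' @export
degree_percent <- function(degree) {
  stopifnot(all(degree >= 0 & degree <= 1))
  as.integer(round(100 * degree))
}
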