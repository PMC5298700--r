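#' The six self-assessment notification types
#'
#' The assessment prompts an EMA client can send: anxiety level, mood rate,
#' positivity of thoughts, self-efficacy, motivation and sleep quality. Each
#' situation rule carries an availability map over these types saying which
#' prompts the user is willing to receive while that situation is active.
#'
#' @return Character vector of the six type names.
#' @export
notification_types <- function() {
  c("anxiety_level", "mood_rate", "positivity_of_thoughts",
    "self_efficacy", "motivation", "sleep_quality")
}

#' Define a situation rule
#'
#' A situation is a tuple of location, time and activity context: an anchor
#' point on the map with one location term, a non-empty subset of day-of-week
#' and time-of-day terms, a non-empty subset of activity classes, and an
#' availability map over the six notification types. Multiple terms within a
#' condition are combined by fuzzy OR (maximum); the four conditions combine
#' by product when the rule is evaluated.
#'
#' @param name User-facing label (e.g. `"working"`).
#' @param lat,lon Anchor point in decimal degrees.
#' @param location_term One of `"same_place"`, `"near"`, `"different"`.
#' @param day_terms Non-empty subset of `c("weekday", "weekend")`.
#' @param time_terms Non-empty subset of
#'   `c("dawn", "morning", "afternoon", "night")`.
#' @param activities Non-empty subset of the seven activity classes.
#' @param availability Named logical vector over [notification_types()];
#'   missing types default to `TRUE` (allowed).
#' @param id Optional identifier; defaults to a slug of `name`.
#' @return An object of class `situation_rule`.
#' @examples
#' working <- situation_rule("working", lat = 52.01, lon = 4.36,
#'   location_term = "near", day_terms = "weekday",
#'   time_terms = c("morning", "afternoon"),
#'   activities = c("still", "walking"))
#' @export
situation_rule <- function(name, lat, lon, location_term,
                           day_terms, time_terms, activities,
                           availability = NULL, id = NULL) {
  vocab <- fuzzy_vocabulary()
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.numeric(lat) || !is.numeric(lon) ||
      abs(lat) > 90 || abs(lon) > 180) {
    rlang::abort("Anchor must have latitude in [-90, 90], longitude in [-180, 180].")
  }
  location_term <- rlang::arg_match(location_term, vocab$location_terms)
  check_subset <- function(x, universe, what) {
    if (length(x) == 0 || !all(x %in% universe) || anyDuplicated(x)) {
      rlang::abort(sprintf(
        "`%s` must be a non-empty subset of {%s}.", what,
        paste(universe, collapse = ", ")))
    }
    x
  }
  day_terms <- check_subset(day_terms, vocab$day_terms, "day_terms")
  time_terms <- check_subset(time_terms, vocab$time_terms, "time_terms")
  activities <- check_subset(activities, vocab$activity_classes, "activities")
  avail <- stats::setNames(rep(TRUE, 6), notification_types())
  if (!is.null(availability)) {
    if (is.null(names(availability)) ||
        !all(names(availability) %in% notification_types()) ||
        !is.logical(availability)) {
      rlang::abort("`availability` must be a named logical over the notification types.")
    }
    avail[names(availability)] <- availability
  }
  if (is.null(id)) id <- gsub("[^a-z0-9]+", "_", tolower(name))
  structure(
    list(id = id, name = name, lat = as.numeric(lat), lon = as.numeric(lon),
         location_term = location_term, day_terms = day_terms,
         time_terms = time_terms, activities = activities,
         availability = avail),
    class = "situation_rule"
  )
}

#' @export
print.situation_rule <- function(x, ...) {
  cat(sprintf(
    "<situation_rule> %s [%s]\n  anchor (%.5f, %.5f), %s\n  day: %s | time: %s\n  activities: %s\n",
    x$name, x$id, x$lat, x$lon, x$location_term,
    paste(x$day_terms, collapse = " | "),
    paste(x$time_terms, collapse = " | "),
    paste(x$activities, collapse = " | ")))
  invisible(x)
}

#' Create an empty situation-rule store
#'
#' Rules are kept in a tibble with one row per situation and list-columns for
#' the multi-valued terms, so the store pipes through dplyr verbs.
#'
#' @return A zero-row tibble of class `situation_rules`.
#' @export
situation_rules <- function() {
  out <- tibble::tibble(
    id = character(), name = character(),
    lat = numeric(), lon = numeric(),
    location_term = character(),
    day_terms = list(), time_terms = list(), activities = list(),
    availability = list()
  )
  class(out) <- c("situation_rules", class(out))
  out
}

rule_as_row <- function(rule) {
  tibble::tibble(
    id = rule$id, name = rule$name, lat = rule$lat, lon = rule$lon,
    location_term = rule$location_term,
    day_terms = list(rule$day_terms), time_terms = list(rule$time_terms),
    activities = list(rule$activities), availability = list(rule$availability)
  )
}

# Anchor comparison tolerance for doubt detection: 1 m, absorbing float
# round-trips through JSON.
DOUBT_ANCHOR_TOL_M <- 1

#' Add a situation rule to a store
#'
#' Persists a rule, guarding against the "case of doubt": a new rule that is
#' identical to a stored one except that one uses `same_place` and the other
#' `near` (same anchor to within 1 m, same day, time and activity terms) can
#' tie in activation whenever the user is within 100 m of the anchor. Adding
#' such a twin raises a classed error (`situfuzz_doubt`) so the definition
#' can be changed; pass `override_doubt = TRUE` to keep it anyway, in which
#' case the twin situations will be identified simultaneously.
#'
#' @param rules A [situation_rules()] store.
#' @param rule A [situation_rule()].
#' @param override_doubt Keep a doubt-twin rule instead of erroring.
#' @return The store with the rule appended.
#' @export
add_situation <- function(rules, rule, override_doubt = FALSE) {
  stopifnot(inherits(rules, "situation_rules"),
            inherits(rule, "situation_rule"))
  if (rule$id %in% rules$id) {
    rlang::abort(sprintf("Duplicate rule id '%s'.", rule$id))
  }
  if (!override_doubt && nrow(rules) > 0) {
    twin <- purrr::map_lgl(seq_len(nrow(rules)), function(i) {
      other <- rules[i, ]
      pair <- sort(c(other$location_term, rule$location_term))
      identical(pair, c("near", "same_place")) &&
        geosphere::distHaversine(c(rule$lon, rule$lat),
                                 c(other$lon, other$lat)) <= DOUBT_ANCHOR_TOL_M &&
        setequal(other$day_terms[[1]], rule$day_terms) &&
        setequal(other$time_terms[[1]], rule$time_terms) &&
        setequal(other$activities[[1]], rule$activities)
    })
    if (any(twin)) {
      rlang::abort(
        sprintf(
          "Rule '%s' differs from '%s' only in same_place vs near: the two can tie whenever the user is within 100 m of the anchor. Pass override_doubt = TRUE to keep it.",
          rule$id, rules$id[which(twin)[1]]),
        class = "situfuzz_doubt")
    }
  }
  out <- dplyr::bind_rows(rules, rule_as_row(rule))
  class(out) <- c("situation_rules", setdiff(class(out), "situation_rules"))
  out
}

#' Remove a situation rule from a store
#'
#' Historical situation records referencing the rule are unaffected; only the
#' definition is dropped.
#'
#' @inheritParams add_situation
#' @param id Identifier of the rule to remove.
#' @return The store without that rule.
#' @export
remove_situation <- function(rules, id) {
  stopifnot(inherits(rules, "situation_rules"))
  if (!id %in% rules$id) rlang::abort(sprintf("Unknown rule id '%s'.", id))
  out <- rules[rules$id != id, ]
  class(out) <- c("situation_rules", setdiff(class(out), "situation_rules"))
  out
}

#' List all defined situations
#'
#' @inheritParams add_situation
#' @return The store as a tibble (one row per rule).
#' @export
get_all_situations <- function(rules) {
  stopifnot(inherits(rules, "situation_rules"))
  rules
}

#' Evaluate situation rules on context snapshots
#'
#' The engine's adapted max-product inference: each rule is evaluated
#' individually against a snapshot. The four condition truths are
#' - location: the location term's membership at the haversine distance from
#'   the snapshot position to the rule anchor, multiplied by the
#'   location-staleness confidence ([location_confidence()]);
#' - day: the maximum membership over the rule's day terms at the snapshot's
#'   day-of-week coordinate;
#' - time: the maximum over its time terms (the night term internally spans
#'   both sides of midnight);
#' - activity: the `on_activity` membership of the summed selected class
#'   probabilities ([activity_input()]).
#' The degree of activation is the product of the four truths.
#'
#' Snapshots with a missing position or missing activity vector cannot be
#' fuzzified; evaluation is declined with a classed error
#' (`situfuzz_suspended`) rather than silently reporting zero degrees.
#'
#' @param snapshots A snapshot tibble from [preprocess()] (one or more rows).
#' @param rules A [situation_rules()] store.
#' @param decay_horizon Seconds over which location confidence decays to
#'   zero; default 27 minutes.
#' @return A tibble with one row per snapshot x rule: `timestamp`, `rule_id`,
#'   `name`, `truth_location`, `truth_day`, `truth_time`, `truth_activity`,
#'   `degree`.
#' @export
evaluate_rules <- function(snapshots, rules, decay_horizon = 27 * 60) {
  stopifnot(inherits(rules, "situation_rules"))
  snapshots <- tibble::as_tibble(snapshots)
  acts <- paste0("a_", fuzzy_vocabulary()$activity_classes)
  required <- c("timestamp", "x_w", "x_t", "lat", "lon", "fix_age", acts)
  missing_cols <- setdiff(required, names(snapshots))
  if (length(missing_cols) > 0) {
    rlang::abort(paste("Snapshot is missing columns:",
                       paste(missing_cols, collapse = ", ")))
  }
  no_loc <- is.na(snapshots$lat) | is.na(snapshots$lon)
  no_act <- Reduce(`|`, lapply(snapshots[acts], is.na))
  if (any(no_loc | no_act)) {
    rlang::abort(
      "Context data unavailable (missing location or activity): inference suspended.",
      class = "situfuzz_suspended")
  }
  if (nrow(rules) == 0 || nrow(snapshots) == 0) {
    return(tibble::tibble(
      timestamp = as.POSIXct(character(), tz = "UTC"),
      rule_id = character(), name = character(),
      truth_location = numeric(), truth_day = numeric(),
      truth_time = numeric(), truth_activity = numeric(),
      degree = numeric()))
  }
  sets <- fuzzy_vocabulary()$sets
  conf <- location_confidence(snapshots$fix_age, horizon = decay_horizon)
  actmat <- as.matrix(snapshots[acts])
  colnames(actmat) <- sub("^a_", "", colnames(actmat))
  purrr::map_dfr(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    dist <- geosphere::distHaversine(
      cbind(snapshots$lon, snapshots$lat), c(r$lon, r$lat))
    t_loc <- eval_membership(sets[[r$location_term]], dist) * conf
    t_day <- do.call(pmax, lapply(r$day_terms[[1]], function(term)
      eval_membership(sets[[term]], snapshots$x_w)))
    t_time <- do.call(pmax, lapply(r$time_terms[[1]], function(term)
      eval_membership(sets[[term]], snapshots$x_t)))
    a_in <- pmin(1, rowSums(actmat[, r$activities[[1]], drop = FALSE]))
    t_act <- eval_membership(sets$on_activity, a_in)
    tibble::tibble(
      timestamp = snapshots$timestamp, rule_id = r$id, name = r$name,
      truth_location = t_loc, truth_day = t_day, truth_time = t_time,
      truth_activity = t_act,
      degree = t_loc * t_day * t_time * t_act)
  })
}

#' Active situations for one snapshot
#'
#' All and only the rules with degree of activation strictly greater than
#' zero, sorted by decreasing degree with rule id as the deterministic
#' tie-break.
#'
#' @param snapshot A single-row snapshot tibble.
#' @inheritParams evaluate_rules
#' @return Tibble of activations with `degree > 0`.
#' @export
get_active_situations <- function(snapshot, rules, decay_horizon = 27 * 60) {
  if (nrow(tibble::as_tibble(snapshot)) != 1) {
    rlang::abort("`snapshot` must have exactly one row.")
  }
  evaluate_rules(snapshot, rules, decay_horizon) |>
    dplyr::filter(.data$degree > 0) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$rule_id)
}

# Degrees within this of the maximum are tied: absorbs float noise in
# products of memberships.
ARGMAX_TOL <- 1e-9

#' Current situation(s) for one snapshot
#'
#' The current situation is the rule (or rules — equal degrees are allowed,
#' e.g. the same_place/near doubt pair) with the highest degree of activation
#' among all defined rules. Empty when no rule has positive degree.
#'
#' @inheritParams get_active_situations
#' @return Character vector of rule ids (possibly empty), sorted by id.
#' @export
current_situation <- function(snapshot, rules, decay_horizon = 27 * 60) {
  act <- get_active_situations(snapshot, rules, decay_horizon)
  if (nrow(act) == 0) return(character())
  sort(act$rule_id[act$degree >= max(act$degree) - ARGMAX_TOL])
}
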