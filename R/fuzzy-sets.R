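#' Construct a piecewise-linear fuzzy set
#'
#' A fuzzy set is a named membership function \eqn{\mu(x) \in [0,1]} over one
#' of four crisp domains: day of week (`[0,7)`, Sunday = 0), time of day
#' (`[0,24)` hours), distance from an anchor point in metres, or a
#' unit-interval activity level. Membership is piecewise linear between
#' ordered breakpoints; on cyclic domains (day, time) the input is reduced
#' modulo the period so the function wraps across midnight / the week
#' boundary, while on acyclic domains the function is constant beyond the
#' extreme breakpoints.
#'
#' @param name Label of the linguistic term (e.g. `"night"`, `"near"`).
#' @param domain One of `"day_of_week"`, `"time_of_day"`, `"distance_m"`,
#'   `"activity_level"`.
#' @param breakpoints Data frame with columns `x` (strictly increasing) and
#'   `mu` (in `[0,1]`) giving the vertices of the membership function.
#' @param cyclic Should the domain wrap? Defaults to `TRUE` for the two
#'   clock-like domains. Cyclic sets must take equal values at `x = 0` and
#'   `x = period`.
#'
#' @return An object of class `fuzzy_set`.
#' @examples
#' night <- fuzzy_set("night", "time_of_day",
#'   data.frame(x = c(0, 1, 3, 19, 21, 24), mu = c(1, 1, 0, 0, 1, 1)))
#' eval_membership(night, c(22, 20, 12))
#' @export
fuzzy_set <- function(name, domain, breakpoints,
                      cyclic = domain %in% c("day_of_week", "time_of_day")) {
  domain <- rlang::arg_match(domain, c("day_of_week", "time_of_day",
                                       "distance_m", "activity_level"))
  bp <- tibble::as_tibble(breakpoints)
  stopifnot(all(c("x", "mu") %in% names(bp)), nrow(bp) >= 2)
  if (is.unsorted(bp$x, strictly = TRUE)) {
    rlang::abort("`breakpoints$x` must be strictly increasing.")
  }
  if (any(bp$mu < 0 | bp$mu > 1)) {
    rlang::abort("`breakpoints$mu` must lie in [0, 1].")
  }
  period <- switch(domain, day_of_week = 7, time_of_day = 24, NA_real_)
  if (cyclic) {
    if (is.na(period)) {
      rlang::abort("Only day_of_week and time_of_day domains can be cyclic.")
    }
    if (bp$x[1] != 0 || bp$x[nrow(bp)] != period ||
        bp$mu[1] != bp$mu[nrow(bp)]) {
      rlang::abort(
        "Cyclic sets need breakpoints spanning [0, period] with equal end values.")
    }
  }
  structure(
    list(name = name, domain = domain, breakpoints = bp,
         cyclic = cyclic, period = period),
    class = "fuzzy_set"
  )
}

#' @export
print.fuzzy_set <- function(x, ...) {
  cat(sprintf("<fuzzy_set> %s on %s%s, %d breakpoints\n",
              x$name, x$domain, if (x$cyclic) " (cyclic)" else "",
              nrow(x$breakpoints)))
  invisible(x)
}

#' Evaluate a fuzzy membership function
#'
#' Returns \eqn{\mu(x)} for a vector of crisp inputs. Cyclic sets reduce the
#' input modulo their period (7 days or 24 hours); acyclic sets hold the
#' membership constant beyond their extreme breakpoints.
#'
#' @param set A [fuzzy_set()].
#' @param x Numeric vector of crisp values on the set's domain.
#' @return Numeric vector of truth values in `[0, 1]`.
#' @export
eval_membership <- function(set, x) {
  stopifnot(inherits(set, "fuzzy_set"))
  if (!is.numeric(x)) rlang::abort("`x` must be numeric.")
  if (any(!is.finite(x))) rlang::abort("`x` must be finite (no NaN/NA/Inf).")
  if (set$cyclic) x <- x %% set$period
  stats::approx(set$breakpoints$x, set$breakpoints$mu, xout = x,
                method = "linear", rule = 2)$y
}

# Standard term shapes. The clock-like sets follow the engine's published
# piecewise forms: night and weekend each wrap the domain boundary (their two
# half-sets are fused into one cyclic function), weekday is the exact
# complement of weekend, and the daytime trapezoids use 2-h ramps so adjacent
# terms cross at 0.5.
standard_sets <- function() {
  list(
    # time of day [0, 24)
    night = fuzzy_set("night", "time_of_day", data.frame(
      x = c(0, 1, 3, 19, 21, 24), mu = c(1, 1, 0, 0, 1, 1))),
    dawn = fuzzy_set("dawn", "time_of_day", data.frame(
      x = c(0, 1, 3, 4, 6, 24), mu = c(0, 0, 1, 1, 0, 0))),
    morning = fuzzy_set("morning", "time_of_day", data.frame(
      x = c(0, 4, 6, 12, 14, 24), mu = c(0, 0, 1, 1, 0, 0))),
    afternoon = fuzzy_set("afternoon", "time_of_day", data.frame(
      x = c(0, 12, 14, 17, 19, 24), mu = c(0, 0, 1, 1, 0, 0))),
    # day of week [0, 7), Sunday = 0
    weekend = fuzzy_set("weekend", "day_of_week", data.frame(
      x = c(0, 0.7, 1.3, 5.7, 6.3, 7), mu = c(1, 1, 0, 0, 1, 1))),
    weekday = fuzzy_set("weekday", "day_of_week", data.frame(
      x = c(0, 0.7, 1.3, 5.7, 6.3, 7), mu = c(0, 0, 1, 1, 0, 0))),
    # location distance in metres: same_place is a subset of near
    same_place = fuzzy_set("same_place", "distance_m", data.frame(
      x = c(0, 100, 300), mu = c(1, 1, 0)), cyclic = FALSE),
    near = fuzzy_set("near", "distance_m", data.frame(
      x = c(0, 800, 1200), mu = c(1, 1, 0)), cyclic = FALSE),
    different = fuzzy_set("different", "distance_m", data.frame(
      x = c(0, 800, 1200), mu = c(0, 0, 1)), cyclic = FALSE),
    # single "on activity" set: identity on the summed selected probability
    on_activity = fuzzy_set("on_activity", "activity_level", data.frame(
      x = c(0, 1), mu = c(0, 1)), cyclic = FALSE)
  )
}

#' The engine's fuzzy vocabulary
#'
#' The standard linguistic vocabulary: three location terms (`same_place`,
#' `near`, `different`), two day-of-week terms (`weekday`, `weekend`), four
#' time-of-day terms (`dawn`, `morning`, `afternoon`, `night`), the seven
#' recognisable activity classes, and the single `on_activity` fuzzy set that
#' fuzzifies the summed probability of the classes a rule selects.
#'
#' @return An object of class `fuzzy_vocabulary`: a list with elements
#'   `sets` (named list of [fuzzy_set()]s), `location_terms`, `day_terms`,
#'   `time_terms`, `activity_classes` and `activity_sets`.
#' @examples
#' vocab <- fuzzy_vocabulary()
#' eval_membership(vocab$sets$weekend, 6.0)
#' @export
fuzzy_vocabulary <- function() {
  structure(
    list(
      sets = standard_sets(),
      location_terms = c("same_place", "near", "different"),
      day_terms = c("weekday", "weekend"),
      time_terms = c("dawn", "morning", "afternoon", "night"),
      activity_classes = c("in_vehicle", "on_bicycle", "on_foot", "running",
                           "still", "tilting", "walking"),
      activity_sets = "on_activity"
    ),
    class = "fuzzy_vocabulary"
  )
}

#' @export
print.fuzzy_vocabulary <- function(x, ...) {
  cat("<fuzzy_vocabulary>\n")
  cat("  location:", paste(x$location_terms, collapse = ", "), "\n")
  cat("  day:     ", paste(x$day_terms, collapse = ", "), "\n")
  cat("  time:    ", paste(x$time_terms, collapse = ", "), "\n")
  cat("  activity classes:", paste(x$activity_classes, collapse = ", "), "\n")
  invisible(x)
}

#' Truth value of a location term at a distance
#'
#' Fuzzifies the great-circle distance between the current position and a
#' rule's anchor point. `same_place` holds full membership up to 100 m and
#' ramps to zero at 300 m; `near` holds to 800 m and ramps to zero at 1200 m;
#' `different` is the mirror of `near`, reaching full membership at 1200 m.
#' `same_place` is everywhere a subset of `near`.
#'
#' @param term `"same_place"`, `"near"` or `"different"`.
#' @param distance Non-negative distance(s) in metres.
#' @return Truth value(s) in `[0, 1]`.
#' @examples
#' location_truth("same_place", c(50, 200, 400))
#' @export
location_truth <- function(term, distance) {
  vocab <- fuzzy_vocabulary()
  term <- rlang::arg_match(term, vocab$location_terms)
  if (!is.numeric(distance) || any(is.na(distance))) {
    rlang::abort("`distance` must be numeric and non-missing.")
  }
  if (any(distance < 0)) rlang::abort("`distance` must be non-negative.")
  eval_membership(vocab$sets[[term]], distance)
}

#' Day-of-week coordinate of a timestamp
#'
#' Maps a timestamp to the cyclic day-of-week scale `[0, 7)` with Sunday = 0,
#' where 24 hours span one unit (Wednesday noon is 3.5). Seconds are
#' discarded; the value has minute resolution.
#'
#' @param timestamp A `POSIXct` vector, or strings parseable as ISO-8601.
#' @return Numeric vector in `[0, 7)`.
#' @export
day_week_value <- function(timestamp) {
  lt <- as_clock_time(timestamp)
  lt$wday + (lt$hour + lt$min / 60) / 24
}

#' Time-of-day coordinate of a timestamp
#'
#' Maps a timestamp to the cyclic hour scale `[0, 24)`, where 60 minutes span
#' one unit (14:30 is 14.5). Seconds are discarded.
#'
#' @inheritParams day_week_value
#' @return Numeric vector in `[0, 24)`.
#' @export
time_of_day_value <- function(timestamp) {
  lt <- as_clock_time(timestamp)
  lt$hour + lt$min / 60
}

# Parse to POSIXlt in UTC; errors on unparseable input.
as_clock_time <- function(timestamp) {
  if (is.character(timestamp)) {
    parsed <- as.POSIXct(timestamp, tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                        "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                        "%Y-%m-%d"),
                         optional = TRUE)
    if (any(is.na(parsed) & !is.na(timestamp))) {
      bad <- timestamp[is.na(parsed) & !is.na(timestamp)][1]
      rlang::abort(sprintf("Unparseable timestamp: '%s'", bad))
    }
    timestamp <- parsed
  }
  if (!inherits(timestamp, c("POSIXct", "POSIXlt"))) {
    rlang::abort("`timestamp` must be POSIXct or an ISO-8601 string.")
  }
  if (any(is.na(timestamp))) rlang::abort("`timestamp` contains NA.")
  as.POSIXlt(timestamp, tz = "UTC")
}

#' Fuzzy input value for the activity condition
#'
#' The crisp input to the `on_activity` set is the sum of the normalised
#' recognition probabilities of the activity classes a rule selects,
#' truncated at one: classes are not mutually exclusive, so the raw sum can
#' exceed full certainty.
#'
#' @param probabilities Named numeric vector of per-class probabilities in
#'   `[0, 1]` (names from the seven activity classes).
#' @param selected Character vector: non-empty subset of the activity classes.
#' @return A single value in `[0, 1]`.
#' @examples
#' p <- c(in_vehicle = 0, on_bicycle = 0, on_foot = 0, running = 0.3,
#'        still = 0, tilting = 0, walking = 0.6)
#' activity_input(p, c("walking", "running"))
#' @export
activity_input <- function(probabilities, selected) {
  classes <- fuzzy_vocabulary()$activity_classes
  if (length(selected) == 0) rlang::abort("`selected` must be non-empty.")
  if (!all(selected %in% classes)) {
    rlang::abort("`selected` contains unknown activity classes.")
  }
  if (is.null(names(probabilities)) ||
      !all(selected %in% names(probabilities))) {
    rlang::abort("`probabilities` must be named and cover the selected classes.")
  }
  p <- probabilities[selected]
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    rlang::abort("Probabilities must lie in [0, 1].")
  }
  min(1, sum(p))
}

#' Count the distinct rule-antecedent forms of a vocabulary
#'
#' Enumerates every combination of one location term, one time-of-day term,
#' one day-of-week term and one activity set — the distinct antecedent shapes
#' a situation rule can take before anchors and activity subsets are filled
#' in. The standard vocabulary yields 3 x 4 x 2 x 1 = 24 forms.
#'
#' @param vocabulary A [fuzzy_vocabulary()], possibly with restricted term
#'   lists.
#' @return Integer count of distinct antecedent combinations.
#' @examples
#' enumerate_antecedent_forms(fuzzy_vocabulary())
#' @export
enumerate_antecedent_forms <- function(vocabulary = fuzzy_vocabulary()) {
  grid <- tidyr::expand_grid(
    location = vocabulary$location_terms,
    time = vocabulary$time_terms,
    day = vocabulary$day_terms,
    activity = vocabulary$activity_sets
  )
  nrow(dplyr::distinct(grid))
}

#' Tabulate membership functions for plotting or export
#'
#' @param vocabulary A [fuzzy_vocabulary()].
#' @param domain Which domain to tabulate.
#' @param n Grid size.
#' @return A tibble with columns `term`, `x`, `mu`.
#' @export
membership_grid <- function(vocabulary = fuzzy_vocabulary(),
                            domain = c("time_of_day", "day_of_week",
                                       "distance_m", "activity_level"),
                            n = 501) {
  domain <- rlang::arg_match(domain)
  sets <- purrr::keep(vocabulary$sets, ~ .x$domain == domain)
  xmax <- switch(domain, time_of_day = 24, day_of_week = 7,
                 distance_m = 1500, activity_level = 1)
  xs <- seq(0, xmax, length.out = n)
  purrr::map_dfr(sets, function(s) {
    tibble::tibble(term = s$name, x = xs, mu = eval_membership(s, xs))
  })
}
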