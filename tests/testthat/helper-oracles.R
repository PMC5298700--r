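# Independent oracles and fixture builders, kept deliberately naive.

# Branch-by-branch transcriptions of the published piecewise formulas for
# the two boundary-wrapping sets. The "1 if 21 < x <= 1" branch is the
# wrapped plateau x in (21, 24] u [0, 1]; likewise "1 if 0.7 >= x > 6.3".
oracle_night <- function(x) {
  vapply(x %% 24, function(xi) {
    if (xi > 3 && xi <= 19) 0
    else if (xi > 19 && xi <= 21) (xi - 19) / 2
    else if (xi > 1 && xi <= 3) (3 - xi) / 2
    else 1  # xi > 21 or xi <= 1
  }, numeric(1))
}

oracle_weekend <- function(x) {
  vapply(x %% 7, function(xi) {
    if (xi > 1.3 && xi <= 5.7) 0
    else if (xi > 5.7 && xi <= 6.3) (xi - 5.7) / 0.6
    else if (xi > 0.7 && xi <= 1.3) (1.3 - xi) / 0.6
    else 1  # xi <= 0.7 or xi > 6.3
  }, numeric(1))
}

ACT_CLASSES <- c("in_vehicle", "on_bicycle", "on_foot", "running",
                 "still", "tilting", "walking")

# Build a one-row snapshot directly from engine coordinates.
make_snapshot <- function(x_w = 3, x_t = 10, lat = 52, lon = 4.3,
                          fix_age = 0, battery = 0.9,
                          activity = c(still = 1)) {
  snap <- tibble::tibble(
    timestamp = as.POSIXct("2017-01-04 10:00:00", tz = "UTC"),
    x_w = x_w, x_t = x_t, lat = lat, lon = lon,
    fix_age = fix_age, battery = battery)
  for (cls in ACT_CLASSES) {
    snap[[paste0("a_", cls)]] <-
      if (cls %in% names(activity)) unname(activity[cls]) else 0
  }
  snap
}

# Naive single-rule evaluator: expands every max and product with explicit
# loops over terms, independent of the vectorised engine path.
naive_evaluate <- function(rule_row, snap, decay_horizon = 27 * 60) {
  sets <- fuzzy_vocabulary()$sets
  dist <- geosphere::distHaversine(c(snap$lon, snap$lat),
                                   c(rule_row$lon, rule_row$lat))
  conf <- max(0, 1 - snap$fix_age / decay_horizon)
  t_loc <- eval_membership(sets[[rule_row$location_term]], dist) * conf
  t_day <- 0
  for (term in rule_row$day_terms[[1]]) {
    t_day <- max(t_day, eval_membership(sets[[term]], snap$x_w))
  }
  t_time <- 0
  for (term in rule_row$time_terms[[1]]) {
    t_time <- max(t_time, eval_membership(sets[[term]], snap$x_t))
  }
  a_sum <- 0
  for (cls in rule_row$activities[[1]]) {
    a_sum <- a_sum + snap[[paste0("a_", cls)]]
  }
  t_act <- eval_membership(sets$on_activity, min(1, a_sum))
  t_loc * t_day * t_time * t_act
}

# Longitude that sits `m` metres east of (lat, lon).
metres_east <- function(lat, lon, m) {
  lon + m / (111320 * cos(lat * pi / 180))
}

# A compact two-rule store around distinct anchors.
tiny_rules <- function() {
  store <- situation_rules()
  store <- add_situation(store, situation_rule(
    "home_rest", lat = 52.0, lon = 4.30, location_term = "same_place",
    day_terms = c("weekday", "weekend"), time_terms = "night",
    activities = "still"))
  add_situation(store, situation_rule(
    "working", lat = 52.0, lon = 4.3438, location_term = "near",
    day_terms = "weekday", time_terms = c("morning", "afternoon"),
    activities = c("still", "walking"),
    availability = c(sleep_quality = FALSE)))
}

# Raw-observation row(s) for context/scheduler tests.
make_raw <- function(timestamp = "2017-01-04 10:00:00", lat = 52, lon = 4.3,
                     alt = 10, fix_time = timestamp, battery = 0.9,
                     still = 100, walking = 0, n = 1) {
  raw <- tibble::tibble(
    timestamp = timestamp, lat = lat, lon = lon, alt = alt,
    fix_time = fix_time, battery = battery,
    p_in_vehicle = 0, p_on_bicycle = 0, p_on_foot = 0, p_running = 0,
    p_still = still, p_tilting = 0, p_walking = walking)
  raw[rep(1, n), ]
}
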