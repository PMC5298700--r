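test_that("degree is the product of the four condition truths", {
  rules <- tiny_rules()
  # all-one conditions: still at home anchor, Wednesday night
  snap <- make_snapshot(x_w = 3.5, x_t = 22, lat = 52.0, lon = 4.30,
                        activity = c(still = 1))
  res <- evaluate_rules(snap, rules)
  home <- res[res$rule_id == "home_rest", ]
  expect_equal(home$degree, 1)
  expect_equal(home$truth_location, 1)
  # mixed conditions multiply: near-work ramp 0.8, activity 0.5
  store <- situation_rules()
  store <- add_situation(store, situation_rule(
    "r", lat = 52.0, lon = 4.30, location_term = "near",
    day_terms = "weekday", time_terms = "morning", activities = "walking"))
  d880 <- metres_east(52.0, 4.30, 880)
  snap2 <- make_snapshot(x_w = 3.0, x_t = 10, lat = 52.0, lon = d880,
                         activity = c(walking = 0.5))
  res2 <- evaluate_rules(snap2, store)
  expect_equal(res2$truth_location, 0.8, tolerance = 1e-3)
  expect_equal(res2$truth_day, 1)
  expect_equal(res2$truth_time, 1)
  expect_equal(res2$truth_activity, 0.5)
  expect_equal(res2$degree,
               res2$truth_location * res2$truth_day * res2$truth_time *
                 res2$truth_activity)
  expect_lte(res2$degree, min(res2$truth_location, res2$truth_day,
                              res2$truth_time, res2$truth_activity))
})

test_that("the worked weekday-morning rule peaks exactly on its printed region", {
  store <- situation_rules()
  store <- add_situation(store, situation_rule(
    "working", lat = 52.0, lon = 4.30, location_term = "near",
    day_terms = "weekday", time_terms = c("morning", "afternoon"),
    activities = c("walking", "running")))
  at_dist <- function(d) metres_east(52.0, 4.30, d)
  # Wednesday 10:00, 400 m out, walking with certainty -> full activation
  snap <- make_snapshot(x_w = 3 + 10 / 24, x_t = 10, lat = 52.0,
                        lon = at_dist(400), activity = c(walking = 1))
  expect_equal(evaluate_rules(snap, store)$degree, 1)
  # full activation across the region: distance <= 800, day in (1.3, 5.7],
  # time in [6,12] u [14,17], activity input 1
  corners <- expand.grid(d = c(0, 400, 799), x_w = c(1.31, 3.5, 5.7),
                         x_t = c(6, 9, 12, 14, 17))
  for (i in seq_len(nrow(corners))) {
    snap_i <- make_snapshot(x_w = corners$x_w[i], x_t = corners$x_t[i],
                            lat = 52.0, lon = at_dist(corners$d[i]),
                            activity = c(walking = 0.7, running = 0.6))
    expect_equal(evaluate_rules(snap_i, store)$degree, 1,
                 label = paste("corner", i))
  }
  # just outside each face the degree drops below 1
  outside <- list(
    make_snapshot(x_w = 3.5, x_t = 10, lat = 52.0, lon = at_dist(900),
                  activity = c(walking = 1)),
    make_snapshot(x_w = 6.0, x_t = 10, lat = 52.0, lon = at_dist(100),
                  activity = c(walking = 1)),
    make_snapshot(x_w = 3.5, x_t = 13, lat = 52.0, lon = at_dist(100),
                  activity = c(walking = 1)),
    make_snapshot(x_w = 3.5, x_t = 10, lat = 52.0, lon = at_dist(100),
                  activity = c(walking = 0.8)))
  for (s in outside) expect_lt(evaluate_rules(s, store)$degree, 1)
})

test_that("active situations are thresholded at zero and sorted", {
  snap <- make_snapshot(x_w = 3.5, x_t = 22, activity = c(still = 1))
  expect_equal(nrow(get_active_situations(snap, situation_rules())), 0)
  rules <- tiny_rules()  # night-home fires, weekday-work does not (22:00)
  act <- get_active_situations(snap, rules)
  expect_equal(act$rule_id, "home_rest")
  expect_true(all(act$degree > 0))
  # a same_place/near doubt twin within 100 m activates identically
  twin <- add_situation(tiny_rules(), situation_rule(
    "home_twin", lat = 52.0, lon = 4.30, location_term = "near",
    day_terms = c("weekday", "weekend"), time_terms = "night",
    activities = "still"), override_doubt = TRUE)
  act2 <- get_active_situations(snap, twin)
  expect_setequal(act2$rule_id, c("home_rest", "home_twin"))
  expect_equal(act2$degree[1], act2$degree[2])
  expect_equal(act2$rule_id, sort(act2$rule_id))  # id tie-break
})

test_that("current situation is the argmax set, empty when nothing fires", {
  rules <- tiny_rules()
  night_home <- make_snapshot(x_w = 3.5, x_t = 22, activity = c(still = 1))
  expect_equal(current_situation(night_home, rules), "home_rest")
  # tie: doubt twin at the anchor
  twin <- add_situation(rules, situation_rule(
    "home_twin", lat = 52.0, lon = 4.30, location_term = "near",
    day_terms = c("weekday", "weekend"), time_terms = "night",
    activities = "still"), override_doubt = TRUE)
  expect_equal(current_situation(night_home, twin),
               c("home_rest", "home_twin"))
  # nothing fires on a weekday noon far from every anchor
  far <- make_snapshot(x_w = 3.5, x_t = 22, lat = 40, lon = -70,
                       activity = c(walking = 1))
  expect_equal(current_situation(far, rules), character())
})

test_that("rule maintenance stores, raises doubt, overrides and removes", {
  store <- situation_rules()
  r1 <- situation_rule("gym", lat = 51.9, lon = 4.5, location_term = "same_place",
                       day_terms = "weekday", time_terms = "night",
                       activities = c("walking", "running"))
  store <- add_situation(store, r1)
  expect_equal(nrow(store), 1)
  expect_error(add_situation(store, r1), "Duplicate")
  # near-twin differing only in the location term raises the doubt exception
  twin <- situation_rule("gym2", lat = 51.9, lon = 4.5, location_term = "near",
                         day_terms = "weekday", time_terms = "night",
                         activities = c("running", "walking"))
  expect_error(add_situation(store, twin), class = "situfuzz_doubt")
  store2 <- add_situation(store, twin, override_doubt = TRUE)
  expect_equal(nrow(store2), 2)
  # a near/different pair is not a doubt case
  diff_rule <- situation_rule("gym3", lat = 51.9, lon = 4.5,
                              location_term = "different",
                              day_terms = "weekday", time_terms = "night",
                              activities = c("walking", "running"))
  expect_no_error(add_situation(store, diff_rule))
  # removal round-trips
  before <- get_all_situations(store)
  store3 <- remove_situation(add_situation(store, twin, override_doubt = TRUE),
                             "gym2")
  expect_equal(get_all_situations(store3), before)
  expect_error(remove_situation(store, "nope"), "Unknown")
})

test_that("rule construction rejects invalid tuples", {
  expect_error(situation_rule("x", lat = 95, lon = 0, location_term = "near",
                              day_terms = "weekday", time_terms = "night",
                              activities = "still"), "latitude")
  expect_error(situation_rule("x", lat = 0, lon = 0, location_term = "near",
                              day_terms = character(), time_terms = "night",
                              activities = "still"), "non-empty")
  expect_error(situation_rule("x", lat = 0, lon = 0, location_term = "near",
                              day_terms = "weekday", time_terms = "someday",
                              activities = "still"), "subset")
  expect_error(situation_rule("x", lat = 0, lon = 0, location_term = "near",
                              day_terms = "weekday", time_terms = "night",
                              activities = "still",
                              availability = c(lottery = TRUE)), "notification")
})

test_that("missing context declines evaluation with a suspension signal", {
  rules <- tiny_rules()
  no_loc <- make_snapshot(); no_loc$lat <- NA_real_
  expect_error(evaluate_rules(no_loc, rules), class = "situfuzz_suspended")
  no_act <- make_snapshot(); no_act$a_still <- NA_real_
  expect_error(evaluate_rules(no_act, rules), class = "situfuzz_suspended")
  expect_error(current_situation(no_loc, rules), class = "situfuzz_suspended")
})

test_that("engine matches a naive loop-expanded evaluator on random contexts", {
  rules <- withr::with_seed(7, {
    store <- situation_rules()
    for (i in 1:5) {
      vocab <- fuzzy_vocabulary()
      store <- add_situation(store, situation_rule(
        paste0("r", i),
        lat = 52 + stats::runif(1, -0.02, 0.02),
        lon = 4.3 + stats::runif(1, -0.02, 0.02),
        location_term = sample(vocab$location_terms, 1),
        day_terms = sample(vocab$day_terms, sample(1:2, 1)),
        time_terms = sample(vocab$time_terms, sample(1:4, 1)),
        activities = sample(vocab$activity_classes, sample(1:7, 1))),
        override_doubt = TRUE)
    }
    store
  })
  snaps <- withr::with_seed(8, {
    purrr::map(1:1000, function(i) {
      acts <- stats::setNames(stats::runif(7), ACT_CLASSES)
      make_snapshot(x_w = stats::runif(1, 0, 7),
                    x_t = stats::runif(1, 0, 24),
                    lat = 52 + stats::runif(1, -0.03, 0.03),
                    lon = 4.3 + stats::runif(1, -0.03, 0.03),
                    fix_age = stats::runif(1, 0, 2000),
                    activity = acts)
    })
  })
  for (snap in snaps[1:25]) {   # dense cross-check on a subset
    res <- evaluate_rules(snap, rules)
    for (i in seq_len(nrow(rules))) {
      expect_equal(res$degree[res$rule_id == rules$id[i]],
                   naive_evaluate(rules[i, ], snap), tolerance = 1e-12)
    }
  }
  # vectorised bulk check on all 1000, rule by rule
  big <- dplyr::bind_rows(snaps)
  res <- evaluate_rules(big, rules)
  for (i in seq_len(nrow(rules))) {
    mine <- res$degree[res$rule_id == rules$id[i]]
    ref <- purrr::map_dbl(seq_len(nrow(big)),
                          ~ naive_evaluate(rules[i, ], big[.x, ]))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("evaluation is order-independent and anchor-sensitive", {
  rules <- tiny_rules()
  snap <- make_snapshot(x_w = 3.5, x_t = 22, activity = c(still = 1))
  res_fwd <- evaluate_rules(snap, rules)
  rev_rules <- rules[2:1, ]
  class(rev_rules) <- class(rules)
  res_rev <- evaluate_rules(snap, rev_rules)
  expect_equal(dplyr::arrange(res_fwd, rule_id),
               dplyr::arrange(res_rev, rule_id))
  # identical rules, anchors 10 km apart: no tie when at one anchor
  store <- situation_rules()
  store <- add_situation(store, situation_rule(
    "a", lat = 52.0, lon = 4.30, location_term = "near",
    day_terms = "weekday", time_terms = "morning", activities = "still"))
  store <- add_situation(store, situation_rule(
    "b", lat = 52.09, lon = 4.30, location_term = "near",
    day_terms = "weekday", time_terms = "morning", activities = "still"))
  at_a <- make_snapshot(x_w = 3.5, x_t = 10, lat = 52.0004, lon = 4.30,
                        activity = c(still = 1))
  res <- evaluate_rules(at_a, store)
  expect_gt(res$degree[res$rule_id == "a"], res$degree[res$rule_id == "b"])
  expect_equal(current_situation(at_a, store), "a")
})
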