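vocab <- fuzzy_vocabulary()

test_that("night and weekend reproduce the published piecewise branches", {
  ws <- vocab$sets$weekend
  ns <- vocab$sets$night
  # plateau / zero-branch spot values
  expect_equal(eval_membership(ws, 3.5), 0)
  expect_equal(eval_membership(ws, 0.0), 1)
  expect_equal(eval_membership(ns, 22.0), 1)
  # hand-evaluated ramps
  expect_equal(eval_membership(ns, 20.0), 0.5)
  expect_equal(eval_membership(ws, 6.0), 0.5)
  expect_equal(eval_membership(ns, 2.0), 0.5)
  expect_equal(eval_membership(ws, 1.0), 0.5)
  # wrapped plateaus cross the domain boundary
  expect_equal(eval_membership(ns, c(21.5, 23.9, 0, 1)), rep(1, 4))
  expect_equal(eval_membership(ws, c(6.5, 6.99, 0, 0.7)), rep(1, 4))
})

test_that("branch-by-branch oracle agrees with the engine on a fine grid", {
  xs_t <- seq(0, 24, by = 0.01)
  expect_true(max(abs(eval_membership(vocab$sets$night, xs_t) -
                        oracle_night(xs_t))) < 1e-12)
  xs_w <- seq(0, 7, by = 0.01)
  expect_true(max(abs(eval_membership(vocab$sets$weekend, xs_w) -
                        oracle_weekend(xs_w))) < 1e-12)
})

test_that("location terms hit their published breakpoints", {
  expect_equal(location_truth("same_place", 50), 1)
  expect_equal(location_truth("same_place", 100), 1)
  expect_equal(location_truth("same_place", 200), 0.5)
  expect_equal(location_truth("same_place", 300), 0)
  expect_equal(location_truth("near", 800), 1)
  expect_equal(location_truth("near", 1000), 0.5)
  expect_equal(location_truth("near", 1200), 0)
  expect_equal(location_truth("different", 1200), 1)
  expect_equal(location_truth("different", 1300), 1)
  expect_equal(location_truth("different", 100), 0)
  expect_error(location_truth("same_place", -5), "non-negative")
  expect_error(location_truth("elsewhere", 5))
})

test_that("timestamps map to day-of-week and time-of-day coordinates", {
  # 2017-01-01 was a Sunday
  expect_equal(day_week_value("2017-01-01 00:00:00"), 0)
  expect_equal(day_week_value("2017-01-04 12:00:00"), 3.5)
  expect_equal(day_week_value("2017-01-07 23:59:00"), 6 + 1439 / 1440)
  expect_equal(time_of_day_value("2017-01-01 00:00:00"), 0)
  expect_equal(time_of_day_value("2017-01-01 14:30:00"), 14.5)
  expect_equal(time_of_day_value("2017-01-01 23:59:00"), 23 + 59 / 60)
  # seconds carry no information
  expect_equal(time_of_day_value("2017-01-01 10:15:42"),
               time_of_day_value("2017-01-01 10:15:00"))
  expect_error(day_week_value("not a time"), "timestamp")
  expect_error(eval_membership(vocab$sets$night, NaN), "finite")
})

test_that("activity input sums selected probabilities and caps at one", {
  p <- c(in_vehicle = 0, on_bicycle = 0, on_foot = 0, running = 0.3,
         still = 0, tilting = 0, walking = 0.6)
  expect_equal(activity_input(p, c("walking", "running")), 0.9)
  p2 <- p; p2["walking"] <- 0.8; p2["still"] <- 0.5
  expect_equal(activity_input(p2, c("walking", "still")), 1)
  expect_equal(activity_input(p * 0, c("walking", "still")), 0)
  expect_error(activity_input(p, character()), "non-empty")
  expect_error(activity_input(p, "flying"), "unknown")
  p3 <- p; p3["still"] <- 1.2
  expect_error(activity_input(p3, "still"), "\\[0, 1\\]")
})

test_that("membership outputs stay in [0,1] and cyclic sets wrap exactly", {
  withr::with_seed(42, {
    for (s in vocab$sets) {
      xmax <- if (s$cyclic) 3 * s$period else 2 * max(s$breakpoints$x)
      xs <- stats::runif(1e5, -xmax, xmax)
      if (s$domain %in% c("distance_m", "activity_level")) xs <- abs(xs)
      mu <- eval_membership(s, xs)
      expect_true(all(mu >= 0 & mu <= 1), label = s$name)
    }
  })
  for (nm in c("night", "dawn", "morning", "afternoon")) {
    xs <- seq(0, 24, by = 0.01)
    expect_equal(eval_membership(vocab$sets[[nm]], xs + 24),
                 eval_membership(vocab$sets[[nm]], xs))
  }
  for (nm in c("weekday", "weekend")) {
    xs <- seq(0, 7, by = 0.01)
    expect_equal(eval_membership(vocab$sets[[nm]], xs + 7),
                 eval_membership(vocab$sets[[nm]], xs))
  }
})

test_that("location terms are monotone and same_place is a subset of near", {
  d <- seq(0, 2000, by = 0.5)
  sp <- location_truth("same_place", d)
  nr <- location_truth("near", d)
  df <- location_truth("different", d)
  expect_true(all(diff(sp) <= 0))
  expect_true(all(diff(nr) <= 0))
  expect_true(all(diff(df) >= 0))
  expect_true(all(sp <= nr))
})

test_that("weekday is the exact complement of weekend", {
  xs <- seq(0, 7, by = 0.001)
  expect_equal(eval_membership(vocab$sets$weekday, xs) +
                 eval_membership(vocab$sets$weekend, xs),
               rep(1, length(xs)))
  # full weekday membership spans exactly the 1.3-5.7 plateau
  expect_equal(eval_membership(vocab$sets$weekday, c(1.3, 3, 5.7)),
               rep(1, 3))
  expect_lt(eval_membership(vocab$sets$weekday, 1.29), 1)
  expect_lt(eval_membership(vocab$sets$weekday, 5.71), 1)
})

test_that("antecedent enumeration matches the vocabulary combinatorics", {
  expect_identical(enumerate_antecedent_forms(fuzzy_vocabulary()), 24L)
  restricted <- fuzzy_vocabulary()
  restricted$location_terms <- "near"
  expect_identical(enumerate_antecedent_forms(restricted), 8L)
  empty <- fuzzy_vocabulary()
  empty$location_terms <- character()
  empty$time_terms <- character()
  empty$day_terms <- character()
  empty$activity_sets <- character()
  expect_identical(enumerate_antecedent_forms(empty), 0L)
})

test_that("fuzzy_set rejects malformed definitions", {
  expect_error(fuzzy_set("bad", "time_of_day",
                         data.frame(x = c(2, 1), mu = c(0, 1))),
               "increasing")
  expect_error(fuzzy_set("bad", "distance_m",
                         data.frame(x = c(0, 1), mu = c(0, 2)),
                         cyclic = FALSE),
               "\\[0, 1\\]")
  expect_error(fuzzy_set("bad", "time_of_day",
                         data.frame(x = c(0, 12), mu = c(0, 1))),
               "period")
})
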