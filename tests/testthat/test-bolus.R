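test_that("insulin on board follows linear decay over the active time", {
  log <- add_event(empty_event_log(), 0, "meal_bolus", delivered = 6)
  expect_equal(insulin_on_board(log, 120, 4), 3.0)
  expect_equal(insulin_on_board(log, 300, 4), 0.0)
  log2 <- add_event(log, 60, "correction_bolus", delivered = 2)
  log2$delivered[log2$kind == "meal_bolus"] <- 4
  expect_equal(insulin_on_board(log2, 120, 4), 4 * 0.5 + 2 * 0.75)
  # basal injections never enter IOB
  log3 <- add_event(log, 60, "basal", delivered = 30)
  expect_equal(insulin_on_board(log3, 120, 4), 3.0)
  expect_equal(insulin_on_board(empty_event_log(), 0, 4), 0)
})

test_that("insulin on board matches a per-minute discretized decay oracle", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    log <- empty_event_log()
    for (i in seq_len(n)) {
      log <- add_event(log, runif(1, 0, 600),
                       sample(c("meal_bolus", "correction_bolus", "basal"), 1),
                       delivered = runif(1, 0.5, 10))
    }
    now <- runif(1, 0, 900)
    ait <- sample(c(3, 4, 5), 1)
    # oracle: walk each rapid dose forward one minute at a time
    oracle <- 0
    for (i in seq_len(nrow(log))) {
      if (!log$kind[i] %in% c("meal_bolus", "correction_bolus")) next
      if (log$time[i] > now) next
      remaining <- log$delivered[i]
      step <- log$delivered[i] / (ait * 60)
      t <- log$time[i]
      while (t < now && remaining > 0) {
        remaining <- remaining - step * min(1, now - t)
        t <- t + 1
      }
      oracle <- oracle + max(0, remaining)
    }
    expect_equal(insulin_on_board(log, now, ait), oracle, tolerance = 1e-9)
  }
})

test_that("trend arrows shift the entered glucose by fixed offsets", {
  expect_equal(trend_adjusted_glucose(8, "stable"), 8)
  expect_equal(trend_adjusted_glucose(8, "rising_fast"), 10.8)
  expect_equal(trend_adjusted_glucose(8, "rising"), 9.4)
  expect_equal(trend_adjusted_glucose(8, "falling"), 6.6)
  expect_equal(trend_adjusted_glucose(1.0, "falling_fast"), 0.1)  # floor
  expect_error(trend_adjusted_glucose(8, "sideways"), "arrow")
  expect_error(trend_adjusted_glucose(-1, "stable"))
})

test_that("meal bolus combines food, correction and IOB as specified", {
  th <- cc_therapy()  # CR 10, ISF 2, target 5.5, 0.5-U pen
  # IOB of exactly 1 U: 2 U taken 2 h ago with AIT 4 h
  log <- add_event(empty_event_log(), 0, "meal_bolus", delivered = 2)
  res <- meal_bolus(th, "lunch", carbs = 60, glucose = 10, arrow = "stable",
                    events = log, now = 120)
  expect_equal(res$iob, 1.0)
  expect_equal(res$raw, 6 + 2.25 - 1)   # food 6, correction 2.25, IOB 1
  expect_equal(res$dose, 7.0)           # 7.25 -> 7.0 at 0.5-U increment
  # null case
  expect_equal(meal_bolus(th, "lunch", carbs = 0, glucose = 5.5)$dose, 0)
  # negative correction reduces a fixed dose
  fd <- fd_therapy()
  res2 <- meal_bolus(fd, "dinner", glucose = 4.0, arrow = "stable")
  expect_equal(res2$raw, 7 - 0.75)
  expect_equal(res2$dose, 6.0)          # 6.25 ties down to 6.0
  # missing glucose refused
  expect_error(meal_bolus(th, "lunch", carbs = 50, glucose = NA_real_),
               "scan")
})

test_that("IOB never eats the food component of a meal bolus", {
  th <- cc_therapy()
  big_iob <- add_event(empty_event_log(), 110, "correction_bolus",
                       delivered = 12)
  res <- meal_bolus(th, "dinner", carbs = 60, glucose = 8, arrow = "stable",
                    events = big_iob, now = 120)
  expect_equal(res$raw, 6.0)  # positive correction fully absorbed, food intact
})

test_that("correction bolus subtracts full IOB and clips at zero", {
  th <- cc_therapy(glucose_target = 6.0)
  expect_equal(correction_bolus(th, glucose = 14)$dose, 4.0)
  expect_equal(correction_bolus(th, glucose = 6)$dose, 0)
  log <- add_event(empty_event_log(), 119, "meal_bolus", delivered = 5.05)
  expect_equal(correction_bolus(th, glucose = 9, events = log, now = 120)$dose, 0)
})

test_that("meal bolus is monotone in carbs, glucose and IOB", {
  th <- cc_therapy()
  set.seed(3)
  for (i in 1:25) {
    carbs <- runif(1, 0, 120); g <- runif(1, 4, 18)
    iob_dose <- runif(1, 0, 6)
    log <- add_event(empty_event_log(), 0, "meal_bolus", delivered = iob_dose)
    base <- meal_bolus(th, "lunch", carbs = carbs, glucose = g,
                       events = log, now = 60)$dose
    expect_gte(meal_bolus(th, "lunch", carbs = carbs + 15, glucose = g,
                          events = log, now = 60)$dose, base)
    expect_gte(meal_bolus(th, "lunch", carbs = carbs, glucose = g + 2,
                          events = log, now = 60)$dose, base)
    log_more <- add_event(empty_event_log(), 0, "meal_bolus",
                          delivered = iob_dose + 3)
    expect_lte(meal_bolus(th, "lunch", carbs = carbs, glucose = g,
                          events = log_more, now = 60)$dose, base)
    expect_equal(base %% th$bolus_increment, 0)
  }
})

test_that("override annotations never change computed doses", {
  th <- cc_therapy()
  log_a <- add_event(empty_event_log(), 0, "meal_bolus", delivered = 4,
                     recommended = 6, override_reason = "exercise")
  log_b <- add_event(empty_event_log(), 0, "meal_bolus", delivered = 4,
                     recommended = 6, override_reason = "none")
  expect_true(log_a$overridden[1])
  expect_equal(meal_bolus(th, "lunch", carbs = 60, glucose = 9,
                          events = log_a, now = 90)$dose,
               meal_bolus(th, "lunch", carbs = 60, glucose = 9,
                          events = log_b, now = 90)$dose)
  expect_error(add_event(empty_event_log(), 0, "meal_bolus", delivered = 4,
                         override_reason = "felt_like_it"), "override")
})

test_that("default meal type follows the time-of-day windows", {
  expect_equal(default_meal_type("07:30"), "breakfast")
  expect_equal(default_meal_type("05:00"), "breakfast")
  expect_equal(default_meal_type("10:59"), "breakfast")
  expect_equal(default_meal_type("12:00"), "lunch")
  expect_equal(default_meal_type("15:59"), "lunch")
  expect_equal(default_meal_type("16:00"), "dinner")
  expect_equal(default_meal_type("20:59"), "dinner")
  expect_equal(default_meal_type("22:15"), "bedtime")
  expect_equal(default_meal_type("03:00"), "bedtime")
  expect_equal(default_meal_type(22 * 60 + 15), "bedtime")
})

test_that("adherence alerts trigger and clear on the stated thresholds", {
  # daily basal logs and plenty of entries: no alerts
  log <- empty_event_log()
  for (d in 0:6) {
    log <- add_event(log, d * 1440 + 540, "basal", delivered = 20)
    for (k in 1:4)
      log <- add_event(log, d * 1440 + 500 + k * 120, "meal_bolus",
                       delivered = 4)
  }
  a <- update_alerts(log, now = 7 * 1440)
  expect_length(a$active, 0)
  # three consecutive days without a basal log
  log2 <- log[!(log$kind == "basal" & log$time >= 4 * 1440), , drop = FALSE]
  a2 <- update_alerts(log2, now = 7 * 1440)
  expect_true("missed_basal" %in% a2$active)
  expect_equal(a2$missed_basal_streak, 3)
  # two missed days do not trigger
  log3 <- log[!(log$kind == "basal" & log$time >= 5 * 1440), , drop = FALSE]
  expect_false("missed_basal" %in% update_alerts(log3, now = 7 * 1440)$active)
  # exactly 3 entries in the trailing 36 h triggers; 4 entries does not
  sparse <- empty_event_log()
  for (k in 1:3) sparse <- add_event(sparse, 1000 + k * 100, "meal_bolus",
                                     delivered = 2)
  expect_true("insufficient_use" %in%
                update_alerts(sparse, now = 1400)$active)
  sparse4 <- add_event(sparse, 1350, "basal", delivered = 20)
  expect_false("insufficient_use" %in%
                 update_alerts(sparse4, now = 1400)$active)
})

test_that("entries can be deleted only within the 30-minute window", {
  log <- add_event(empty_event_log(), 100, "meal_bolus", delivered = 5)
  ok <- delete_entry(log, log$id[1], now = 110)
  expect_true(ok$deleted)
  expect_equal(nrow(ok$log), 0)
  late <- delete_entry(log, log$id[1], now = 131)
  expect_false(late$deleted)
  expect_equal(nrow(late$log), 1)
  expect_equal(delete_entry(log, log$id[1], now = 130)$deleted, TRUE)
  expect_error(delete_entry(ok$log, log$id[1], now = 110), "not found")
})
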