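default_phi <- function() {
  pr <- titration_prior()
  pr$median
}

test_that("the MAP fit is self-consistent on noiseless data from the prior median", {
  phi <- default_phi()
  phys <- patient_physiology(S_I = phi[["S_I"]], G_b = phi[["G_b"]],
                             k_b = phi[["k_b"]],
                             f = c(breakfast = phi[["f_breakfast"]],
                                   lunch = phi[["f_lunch"]],
                                   dinner = phi[["f_dinner"]]))
  th <- cc_therapy(basal_dose = round(steady_state_basal(phys, 7)))
  ctl <- titration_control(assumed_carbs = c(breakfast = 45, lunch = 60,
                                             dinner = 70))
  sw <- simulated_week(phys, th, dt = ctl$dt_fit)
  fit <- fit_patient_model(sw$week, titration_prior(), th, control = ctl)
  expect_true(all(abs(fit$map / phi - 1) < 1e-3))
  expect_gte(fit$r2, 0.999)
})

test_that("pure-noise sensor data yields no confidence and no movement", {
  set.seed(5)
  th <- cc_therapy()
  grid <- seq(0, 7 * 1440, by = 15)
  cgm <- data.frame(time = grid, glucose = 8 + rnorm(length(grid), 0, 2),
                    record_type = "historic", stringsAsFactors = FALSE)
  log <- empty_event_log()
  for (d in 0:6)
    log <- add_event(log, d * 1440 + 750, "meal_bolus", meal = "lunch",
                     delivered = 5, carbs = 60)
  wk <- week_data(cgm, log, start = 0)
  fit <- fit_patient_model(wk, titration_prior(), th)
  expect_lt(max(0, fit$r2), 0.1)
  w <- mditrate:::blend_weights(fit)
  expect_true(all(w < 0.1))
  blended <- blend_therapy(cc_therapy(basal_dose = 40), th, fit)
  expect_equal(blended$basal_dose, th$basal_dose, tolerance = 0.05 * 20)
})

test_that("blending is a log-scale mixture with exact degenerate limits", {
  th_prev <- cc_therapy(basal_dose = 10,
                        carb_ratio = c(breakfast = 8, lunch = 10, dinner = 12))
  th_star <- cc_therapy(basal_dose = 40,
                        carb_ratio = c(breakfast = 16, lunch = 5, dinner = 12))
  w0 <- c(basal = 0, breakfast = 0, lunch = 0, dinner = 0)
  w1 <- c(basal = 1, breakfast = 1, lunch = 1, dinner = 1)
  wh <- c(basal = 0.5, breakfast = 0.5, lunch = 0.5, dinner = 0.5)
  expect_equal(titratable_params(blend_therapy(th_star, th_prev, w0)),
               titratable_params(th_prev))
  expect_equal(titratable_params(blend_therapy(th_star, th_prev, w1)),
               titratable_params(th_star))
  half <- blend_therapy(th_star, th_prev, wh)
  expect_equal(half$basal_dose, 20)                      # geometric mean
  expect_equal(half$carb_ratio[["breakfast"]], sqrt(8 * 16))
})

hypo_week <- function(th, hypo_time = NULL, overnight_low = FALSE) {
  grid <- seq(0, 7 * 1440, by = 15)
  g <- rep(7.5, length(grid))
  if (!is.null(hypo_time)) g[which.min(abs(grid - hypo_time))] <- 3.5
  if (overnight_low) g[which.min(abs(grid - (2 * 1440 + 120)))] <- 3.7
  cgm <- data.frame(time = grid, glucose = g, record_type = "historic",
                    stringsAsFactors = FALSE)
  log <- empty_event_log()
  for (d in 0:6) {
    log <- add_event(log, d * 1440 + 450, "meal_bolus", meal = "breakfast",
                     delivered = 5, carbs = 45)
    log <- add_event(log, d * 1440 + 1110, "meal_bolus", meal = "dinner",
                     delivered = 6, carbs = 70)
  }
  week_data(cgm, log, start = 0)
}

test_that("safety attenuation is one-sided and meal-specific", {
  th_prev <- fd_therapy(fixed_dose = c(breakfast = 8, lunch = 5, dinner = 6))
  ctl <- titration_control()
  # hypo 2 h after day-3 breakfast
  wk <- hypo_week(th_prev, hypo_time = 3 * 1440 + 450 + 120)
  want_more <- fd_therapy(fixed_dose = c(breakfast = 10, lunch = 5, dinner = 7))
  out <- safety_attenuate(want_more, th_prev, wk, ctl)
  expect_equal(out$fixed_dose[["breakfast"]], 8)       # capped
  expect_equal(out$fixed_dose[["dinner"]], 7)          # untouched meal
  expect_true("breakfast" %in% attr(out, "attenuations"))
  # decreases always pass
  want_less <- fd_therapy(fixed_dose = c(breakfast = 6, lunch = 5, dinner = 6))
  out2 <- safety_attenuate(want_less, th_prev, wk, ctl)
  expect_equal(out2$fixed_dose[["breakfast"]], 6)
  # no hypoglycemia anywhere: rule inert
  calm <- hypo_week(th_prev)
  out3 <- safety_attenuate(want_more, th_prev, calm, ctl)
  expect_equal(out3$fixed_dose[["breakfast"]], 10)
  expect_length(attr(out3, "attenuations"), 0)
  # nocturnal reading 3.7 blocks a basal increase but allows a decrease
  night <- hypo_week(th_prev, overnight_low = TRUE)
  up <- fd_therapy(basal_dose = 22,
                   fixed_dose = c(breakfast = 8, lunch = 5, dinner = 6))
  expect_equal(safety_attenuate(up, th_prev, night, ctl)$basal_dose, 20)
  down <- fd_therapy(basal_dose = 18,
                     fixed_dose = c(breakfast = 8, lunch = 5, dinner = 6))
  expect_equal(safety_attenuate(down, th_prev, night, ctl)$basal_dose, 18)
  # a postprandial nadir of 4.2 (never below 3.9) also triggers
  wk42 <- hypo_week(th_prev)
  wk42$cgm$glucose[which.min(abs(wk42$cgm$time - (450 + 60)))] <- 4.2
  out4 <- safety_attenuate(want_more, th_prev, wk42, ctl)
  expect_equal(out4$fixed_dose[["breakfast"]], 8)
})

test_that("finalize caps weekly movement, rounds to pens and flags at 30%", {
  ctl <- titration_control()
  prev <- fd_therapy(basal_dose = 20,
                     fixed_dose = c(breakfast = 5, lunch = 6, dinner = 7))
  ref <- fd_therapy(basal_dose = 18,
                    fixed_dose = c(breakfast = 5, lunch = 6, dinner = 7))
  want <- fd_therapy(basal_dose = 30,
                     fixed_dose = c(breakfast = 5, lunch = 6, dinner = 7))
  rec <- finalize_recommendation(want, prev, ref, ctl)
  expect_equal(rec$therapy$basal_dose, 24)            # 20 * 1.2, on 1-U pen
  # cumulative vs reference 18: 24/18 - 1 = +33% -> flagged
  expect_true(rec$flagged)
  expect_true(rec$approved)                           # auto-approve default
  held <- finalize_recommendation(want, prev, ref,
                                  titration_control(auto_approve = FALSE))
  expect_false(held$approved)
  # no change is an identity and unflagged
  same <- finalize_recommendation(prev, prev, prev, ctl)
  expect_equal(titratable_params(same$therapy), titratable_params(prev))
  expect_false(same$flagged)
})

test_that("rounding never pushes a parameter beyond the weekly cap", {
  ctl <- titration_control()
  set.seed(8)
  for (i in 1:40) {
    prev <- fd_therapy(basal_dose = sample(seq(4, 40, 2), 1),
                       fixed_dose = c(breakfast = sample(seq(1, 12, 0.5), 1),
                                      lunch = 6, dinner = 7),
                       bolus_increment = sample(c(0.5, 1), 1))
    want <- prev
    want$basal_dose <- prev$basal_dose * runif(1, 0.5, 2)
    want$fixed_dose[["breakfast"]] <- prev$fixed_dose[["breakfast"]] *
      runif(1, 0.5, 2)
    rec <- finalize_recommendation(want, prev, prev, ctl)
    p_new <- titratable_params(rec$therapy)
    p_prev <- titratable_params(prev)
    expect_true(all(abs(p_new / p_prev - 1) <= ctl$weekly_cap + 1e-9))
    expect_equal(p_new[["basal"]] %% prev$basal_increment, 0)
    # on the pen grid, unless the (possibly off-grid) predecessor is kept
    bk <- p_new[["breakfast"]]
    on_grid <- abs(bk / prev$bolus_increment -
                     round(bk / prev$bolus_increment)) < 1e-9
    expect_true(on_grid || bk == p_prev[["breakfast"]])
  }
})

test_that("carb-ratio capping works on the insulin scale", {
  ctl <- titration_control()
  prev <- cc_therapy(carb_ratio = c(breakfast = 10, lunch = 10, dinner = 10))
  want <- cc_therapy(carb_ratio = c(breakfast = 5, lunch = 20, dinner = 10))
  rec <- finalize_recommendation(want, prev, prev, ctl)
  # breakfast: insulin capped at +20% -> CR >= 10/1.2 = 8.33 -> rounded to 8.4
  expect_equal(rec$therapy$carb_ratio[["breakfast"]], 8.4)
  # lunch: insulin capped at -20% -> CR <= 12.5
  expect_equal(rec$therapy$carb_ratio[["lunch"]], 12.5)
})

test_that("a degraded-data week returns the therapy unchanged", {
  th <- cc_therapy()
  st <- titration_state(th)
  empty_wk <- week_data(flat_trace(7, days = 0.04), empty_event_log(), start = 0)
  res <- titrate_week(empty_wk, th, st)
  expect_equal(titratable_params(res$recommendation$therapy),
               titratable_params(th))
  expect_false(res$recommendation$flagged)
  expect_match(res$recommendation$rationale, "no change")
})

test_that("an under-basalized patient gets a basal increase and a well-controlled one is left alone", {
  phi <- default_phi()
  phys <- patient_physiology(S_I = phi[["S_I"]], G_b = phi[["G_b"]],
                             k_b = phi[["k_b"]],
                             f = c(breakfast = phi[["f_breakfast"]],
                                   lunch = phi[["f_lunch"]],
                                   dinner = phi[["f_dinner"]]))
  B_star <- steady_state_basal(phys, 6.5)
  ctl <- titration_control(assumed_carbs = c(breakfast = 45, lunch = 60,
                                             dinner = 70))
  # fasting hyperglycemia from half the needed basal
  th_low <- cc_therapy(basal_dose = round(B_star / 2), glucose_target = 6.5,
                       carb_ratio = c(breakfast = 9, lunch = 9, dinner = 9))
  sw <- simulated_week(phys, th_low, dt = ctl$dt_fit)
  res <- titrate_week(sw$week, th_low, titration_state(th_low), control = ctl)
  expect_gt(res$recommendation$therapy$basal_dose, th_low$basal_dose)
})

test_that("repeated noiseless titration drives basal to the closed-form solution", {
  phi <- default_phi()
  phys <- patient_physiology(S_I = phi[["S_I"]], G_b = phi[["G_b"]],
                             k_b = phi[["k_b"]],
                             f = c(breakfast = phi[["f_breakfast"]],
                                   lunch = phi[["f_lunch"]],
                                   dinner = phi[["f_dinner"]]))
  target <- 6.5
  B_star <- steady_state_basal(phys, target)
  th <- cc_therapy(basal_dose = max(2, round(B_star * 0.55)),
                   glucose_target = target,
                   carb_ratio = c(breakfast = 9, lunch = 9, dinner = 9))
  st <- titration_state(th)
  ctl <- titration_control(assumed_carbs = c(breakfast = 45, lunch = 60,
                                             dinner = 70))
  for (wk in 1:8) {
    sw <- simulated_week(phys, th, start = (wk - 1) * 7 * 1440,
                         dt = ctl$dt_fit)
    res <- titrate_week(sw$week, th, st, control = ctl)
    st <- res$state
    th <- res$recommendation$therapy
  }
  expect_lte(abs(th$basal_dose - B_star), th$basal_increment)
})

test_that("a therapy at the cost optimum is a titration fixed point", {
  phi <- default_phi()
  phys <- patient_physiology(S_I = phi[["S_I"]], G_b = phi[["G_b"]],
                             k_b = phi[["k_b"]],
                             f = c(breakfast = phi[["f_breakfast"]],
                                   lunch = phi[["f_lunch"]],
                                   dinner = phi[["f_dinner"]]))
  ctl <- titration_control(assumed_carbs = c(breakfast = 45, lunch = 60,
                                             dinner = 70))
  th0 <- cc_therapy(basal_dose = round(steady_state_basal(phys, 6.5)),
                    glucose_target = 6.5,
                    carb_ratio = c(breakfast = 9, lunch = 9, dinner = 9))
  # derive the in-model optimum from a perfect fit, then round it onto
  # the dosing grids
  sw0 <- simulated_week(phys, th0, dt = ctl$dt_fit)
  fit0 <- fit_patient_model(sw0$week, titration_prior(), th0, control = ctl)
  th_opt <- optimal_therapy(fit0, th0, sw0$week, control = ctl)
  th_opt$basal_dose <- round_to_increment(th_opt$basal_dose,
                                          th_opt$basal_increment)
  th_opt$carb_ratio <- round(th_opt$carb_ratio, 1)
  sw <- simulated_week(phys, th_opt, dt = ctl$dt_fit)
  res <- titrate_week(sw$week, th_opt, titration_state(th_opt), control = ctl)
  rel <- abs(res$recommendation$changes$relative_change)
  expect_true(all(rel < 0.03))
})
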