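# shared fixtures, built in code

cc_therapy <- function(...) {
  args <- modifyList(list(
    basal_dose = 20, meal_strategy = "carb_counting",
    carb_ratio = c(breakfast = 10, lunch = 10, dinner = 10),
    isf = 2, glucose_target = 5.5, active_insulin_time = 4,
    basal_increment = 1.0, bolus_increment = 0.5), list(...))
  do.call(therapy_parameters, args)
}

fd_therapy <- function(...) {
  args <- modifyList(list(
    basal_dose = 20, meal_strategy = "fixed_dose",
    fixed_dose = c(breakfast = 5, lunch = 6, dinner = 7),
    isf = 2, glucose_target = 5.5, active_insulin_time = 4,
    basal_increment = 1.0, bolus_increment = 0.5), list(...))
  do.call(therapy_parameters, args)
}

# flat synthetic CGM trace at a constant glucose over `days`
flat_trace <- function(glucose = 6.5, days = 7, start = 0) {
  times <- seq(start, start + days * 1440, by = 15)
  data.frame(time = times, glucose = glucose, record_type = "historic",
             stringsAsFactors = FALSE)
}

# noiseless week of data simulated from a physiology under a therapy:
# three meals/day, each covered by its programmed food dose
simulated_week <- function(phys, therapy, start = 0, dt = 5,
                           meal_grams = c(breakfast = 45, lunch = 60,
                                          dinner = 70)) {
  log <- empty_event_log()
  meal_times <- c(breakfast = 450, lunch = 750, dinner = 1110)
  for (d in 0:6) {
    for (mt in names(meal_times)) {
      t_m <- start + d * 1440 + meal_times[[mt]]
      cc <- therapy$meal_strategy == "carb_counting"
      food <- if (cc) meal_grams[[mt]] / therapy$carb_ratio[[mt]]
              else therapy$fixed_dose[[mt]]
      dose <- round_to_increment(food, therapy$bolus_increment)
      if (dose > 0)
        log <- add_event(log, t_m, "meal_bolus", meal = mt,
                         delivered = dose,
                         carbs = if (cc) meal_grams[[mt]] else NA_real_,
                         recommended = dose)
    }
  }
  # integrate the whole week with the logged doses and true meals
  meals <- data.frame(
    time = start + rep(0:6, each = 3) * 1440 + rep(unname(meal_times), 7),
    grams = rep(unname(meal_grams), 7),
    meal = rep(names(meal_times), 7), stringsAsFactors = FALSE)
  boluses <- data.frame(time = log$time[log$kind == "meal_bolus"],
                        units = log$delivered[log$kind == "meal_bolus"])
  tr <- simulate_glucose(phys, therapy$basal_dose, boluses = boluses,
                         meals = meals, horizon_days = 7, t0 = start, dt = dt)
  grid <- seq(start, start + 7 * 1440, by = 15)
  cgm <- data.frame(time = grid,
                    glucose = approx(tr$time, tr$glucose, xout = grid)$y,
                    record_type = "historic", stringsAsFactors = FALSE)
  list(cgm = cgm, log = log, trace = tr,
       week = week_data(cgm, log, start = start))
}
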