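#' Cohort generator configuration
#'
#' Population distributions, initial-therapy mis-specification, meal
#' schedule, adherence behaviour and sensor model of the virtual cohort.
#' Defaults emulate adults with type 1 diabetes on multiple daily
#' injections entering a titration trial with suboptimal control:
#' baseline estimated HbA1c at least 7.5 percent, mean about 8.6 and SD
#' about 1.1 across the cohort, about 60 percent carbohydrate counters,
#' 76 percent regular sensor users, a median of about 2.7 prandial
#' calculator uses and 0.92 basal logs per day.
#'
#' @param population log-normal population over the fitted physiology
#'   parameters: list with `median` and `sdlog` for
#'   `S_I, G_b, k_b, f` (one shared bioavailability distribution).
#' @param mis_bias,mis_sd log-scale mean and sd of the multiplicative
#'   error applied to each oracle therapy parameter (insulin scale) to
#'   form the mis-specified initial therapy; the negative bias encodes
#'   clinical under-insulinization of a poorly-controlled cohort and is
#'   the single calibration dial for the baseline HbA1c distribution.
#' @param meal_times,meal_time_sd scheduled clock minutes of breakfast,
#'   lunch, dinner and the per-day jitter sd (minutes).
#' @param meal_grams,meal_grams_sdlog median grams per meal type and the
#'   log-normal day-to-day spread.
#' @param snack_rate mean number of unannounced (never bolused, never
#'   logged) snacks per day; a major driver of chronic hyperglycemia in
#'   this population.
#' @param snack_grams,snack_grams_sdlog median grams per snack and
#'   log-normal spread.
#' @param carb_entry_bias,carb_entry_sd log-scale bias and sd of the
#'   carbohydrate amounts carb-counting participants enter into the app
#'   relative to what they actually eat (systematic under-counting).
#' @param p_carb_counting probability a participant carb-counts (the
#'   rest use fixed doses).
#' @param p_regular_user probability of the regular-sensor-user stratum.
#' @param adherence_bolus,adherence_basal `c(shape1, shape2)` of the
#'   beta distributions of per-participant meal-bolus and basal-log
#'   probabilities.
#' @param p_correction_check per-participant median probability of an
#'   evening correction check.
#' @param p_override_dose probability a calculated dose is overridden.
#' @param isf_median,isf_sdlog prescribed insulin sensitivity factor
#'   distribution, mmol/L per unit.
#' @param isf_severity_coupling how strongly the prescribed ISF lags
#'   with the participant's overall prescription severity (a severely
#'   under-insulinized prescription also carries a too-weak correction
#'   factor).
#' @param absorption_sd log-scale day-to-day variability of subcutaneous
#'   bolus absorption (the effective dose differs from the injected
#'   one).
#' @param glucose_target programmed calculator target, mmol/L.
#' @param oracle_target fasting target used to derive the oracle basal,
#'   mmol/L.
#' @param burn_in_days burn-in length for the baseline estimate, days.
#' @param hba1c_min inclusion threshold on baseline estimated HbA1c, %.
#' @param sensor a [sensor_model()].
#' @param dt_sim simulation step, minutes.
#' @return a config list.
#' @export
cohort_config <- function(
    population = list(
      median = c(S_I = 8e-4, G_b = 17, k_b = 0.7, f = 0.8),
      sdlog = c(S_I = 0.35, G_b = 0.28, k_b = 0.25, f = 0.15)),
    mis_bias = -0.41, mis_shared_sd = 1.00, mis_severity_max = 2.0,
    mis_sd = 0.25,
    meal_times = c(breakfast = 450, lunch = 750, dinner = 1110),
    meal_time_sd = 30,
    meal_grams = c(breakfast = 45, lunch = 60, dinner = 70),
    meal_grams_sdlog = 0.25,
    snack_rate = 1.0, snack_grams = 20, snack_grams_sdlog = 0.4,
    carb_entry_bias = -0.2, carb_entry_sd = 0.25,
    p_carb_counting = 0.60, p_regular_user = 0.76,
    adherence_bolus = c(27, 3), adherence_basal = c(22, 2),
    p_correction_check = 0.40, p_override_dose = 0.03,
    isf_median = 3.5, isf_sdlog = 0.3, isf_severity_coupling = 0.7,
    absorption_sd = 0.25,
    glucose_target = 6.0, oracle_target = 6.5,
    burn_in_days = 14, hba1c_min = 7.5,
    sensor = sensor_model(), dt_sim = 5) {
  list(population = population, mis_bias = mis_bias,
       mis_shared_sd = mis_shared_sd, mis_severity_max = mis_severity_max,
       mis_sd = mis_sd,
       meal_times = meal_times, meal_time_sd = meal_time_sd,
       meal_grams = meal_grams, meal_grams_sdlog = meal_grams_sdlog,
       snack_rate = snack_rate, snack_grams = snack_grams,
       snack_grams_sdlog = snack_grams_sdlog,
       carb_entry_bias = carb_entry_bias, carb_entry_sd = carb_entry_sd,
       p_carb_counting = p_carb_counting, p_regular_user = p_regular_user,
       adherence_bolus = adherence_bolus, adherence_basal = adherence_basal,
       p_correction_check = p_correction_check,
       p_override_dose = p_override_dose,
       isf_median = isf_median, isf_sdlog = isf_sdlog,
       isf_severity_coupling = isf_severity_coupling,
       absorption_sd = absorption_sd,
       glucose_target = glucose_target, oracle_target = oracle_target,
       burn_in_days = burn_in_days, hba1c_min = hba1c_min,
       sensor = sensor, dt_sim = dt_sim)
}

# draw one physiology from the population (kinetics at defaults)
draw_physiology <- function(config) {
  pop <- config$population
  draw <- function(nm) rlnorm(1, log(pop$median[[nm]]), pop$sdlog[[nm]])
  f <- pmin(c(breakfast = draw("f"), lunch = draw("f"), dinner = draw("f")), 1)
  patient_physiology(S_I = draw("S_I"), G_b = draw("G_b"), k_b = draw("k_b"),
                     f = f)
}

# oracle prandial parameter for one meal type: bounded 1-D search of the
# band cost on a one-day replay (meal at its scheduled time, oracle basal)
oracle_prandial <- function(phys, therapy_proto, meal, grams, config) {
  is_cc <- therapy_proto$meal_strategy == "carb_counting"
  meals <- data.frame(time = config$meal_times[[meal]], grams = grams,
                      meal = meal, stringsAsFactors = FALSE)
  objective <- function(v) {
    cand <- therapy_proto
    if (is_cc) cand$carb_ratio[[meal]] <- v else cand$fixed_dose[[meal]] <- v
    g <- replay_week(phys, cand, meals, start = 0, dt = config$dt_sim,
                     horizon_days = 1)
    band_cost(g, c(hypo = 4, hyper = 1))
  }
  bounds <- if (is_cc) c(3, 30) else c(0.5, 25)
  optimize(objective, lower = bounds[1], upper = bounds[2],
           tol = 0.05)$minimum
}

# oracle (well-specified) therapy for a participant's true physiology
oracle_therapy <- function(phys, strategy, isf, increments, config) {
  basal <- steady_state_basal(phys, config$oracle_target)
  proto <- if (strategy == "carb_counting") {
    therapy_parameters(basal, "carb_counting",
                       carb_ratio = c(breakfast = 10, lunch = 10, dinner = 10),
                       isf = isf, glucose_target = config$glucose_target,
                       basal_increment = increments[["basal"]],
                       bolus_increment = increments[["bolus"]])
  } else {
    therapy_parameters(basal, "fixed_dose",
                       fixed_dose = c(breakfast = 4, lunch = 5, dinner = 6),
                       isf = isf, glucose_target = config$glucose_target,
                       basal_increment = increments[["basal"]],
                       bolus_increment = increments[["bolus"]])
  }
  for (mt in c("breakfast", "lunch", "dinner")) {
    v <- oracle_prandial(phys, proto, mt, config$meal_grams[[mt]], config)
    if (strategy == "carb_counting") proto$carb_ratio[[mt]] <- v
    else proto$fixed_dose[[mt]] <- v
  }
  proto
}

# Mis-specify an oracle therapy: a participant-level severity component
# (how badly the whole prescription lags the patient's needs) plus
# independent per-parameter errors, both log-normal on the insulin
# scale; the result is rounded to the dosing grids.
# Participant-level prescription severity: an offset plus a one-sided
# exponential tail on the log insulin scale. The one-sided form mirrors
# a treated clinical population: most prescriptions lag needs modestly,
# a minority severely, none are grossly over-insulinized.
draw_severity <- function(config) {
  excess <- stats::rexp(1, 1 / config$mis_shared_sd)
  # truncate: prescriptions lagging beyond ~4-fold under-dosing do not
  # survive routine clinical contact
  while (excess > config$mis_severity_max)
    excess <- stats::rexp(1, 1 / config$mis_shared_sd)
  config$mis_bias - excess
}

mis_specify <- function(oracle, config, severity = NULL) {
  th <- oracle
  is_cc <- th$meal_strategy == "carb_counting"
  if (is.null(severity)) severity <- draw_severity(config)
  err <- exp(severity + rnorm(4, 0, config$mis_sd))
  th$basal_dose <- max(config$glucose_target,  # keep a plausible floor
                       round_to_increment(th$basal_dose * err[1],
                                          th$basal_increment))
  i <- 2
  for (mt in c("breakfast", "lunch", "dinner")) {
    if (is_cc) {
      th$carb_ratio[[mt]] <- max(1, round(th$carb_ratio[[mt]] / err[i], 1))
    } else {
      # at least one pen increment: an MDI patient doses something at meals
      th$fixed_dose[[mt]] <- max(th$bolus_increment,
                                 round_to_increment(th$fixed_dose[[mt]] * err[i],
                                                    th$bolus_increment))
    }
    i <- i + 1
  }
  th
}

draw_increments <- function() {
  c(basal = sample(c(0.5, 1, 2), 1, prob = c(0.06, 0.89, 0.05)),
    bolus = sample(c(0.5, 1), 1, prob = c(0.22, 0.78)))
}

draw_participant <- function(id, config) {
  phys <- draw_physiology(config)
  strategy <- if (runif(1) < config$p_carb_counting) "carb_counting"
              else "fixed_dose"
  stratum <- if (runif(1) < config$p_regular_user) "regular" else "new"
  severity <- draw_severity(config)
  isf <- rlnorm(1, log(config$isf_median) -
                  config$isf_severity_coupling * severity, config$isf_sdlog)
  increments <- draw_increments()
  oracle <- oracle_therapy(phys, strategy, isf, increments, config)
  therapy <- mis_specify(oracle, config, severity = severity)
  adherence <- list(
    p_bolus = rbeta(1, config$adherence_bolus[1], config$adherence_bolus[2]),
    p_basal = rbeta(1, config$adherence_basal[1], config$adherence_basal[2]),
    p_corr = rbeta(1, 6 * config$p_correction_check, 6 * (1 - config$p_correction_check)),
    p_override_dose = config$p_override_dose,
    snack_rate = rlnorm(1, log(config$snack_rate), 0.6),
    carb_bias = rnorm(1, config$carb_entry_bias, 0.2))
  structure(list(id = id, physiology = phys, therapy = therapy,
                 oracle = oracle, strategy = strategy, stratum = stratum,
                 adherence = adherence, baseline_hba1c = NA_real_),
            class = "virtual_participant")
}

#' Generate a calibrated virtual cohort
#'
#' Draws virtual participants (physiology from the log-normal
#' population, mis-specified initial therapy, adherence profile,
#' sensor-use stratum), runs a burn-in simulation under the initial
#' therapy, converts mean glucose to estimated HbA1c via the glucose
#' management indicator, and rejection-samples until every participant
#' meets the inclusion threshold (estimated HbA1c >= 7.5 percent).
#' Reproducible for a fixed seed.
#'
#' @param n cohort size (>= 2).
#' @param seed integer RNG seed.
#' @param config a [cohort_config()].
#' @return list of `virtual_participant` objects with `baseline_hba1c`
#'   filled in.
#' @export
generate_cohort <- function(n = 84, seed = 20271, config = cohort_config()) {
  stopifnot(n >= 2)
  set.seed(seed)
  cohort <- vector("list", n)
  attempts <- 0L
  for (i in seq_len(n)) {
    repeat {
      attempts <- attempts + 1L
      if (attempts > 100L * n)
        stop("cohort calibration stalled: rejection sampling exceeded ",
             100L * n, " attempts")
      p <- draw_participant(i, config)
      sim <- simulate_participant_days(p, p$therapy, config$burn_in_days,
                                       t0 = 0, config = config)
      mg <- mean(sim$cgm$glucose[sim$cgm$record_type == "historic"])
      a1c <- estimate_hba1c(mg)
      if (a1c >= config$hba1c_min) {
        p$baseline_hba1c <- a1c
        p$baseline_mean_glucose <- mg
        cohort[[i]] <- p
        break
      }
    }
  }
  # cohort composition (not an individual trait): exactly the configured
  # share of regular sensor users, randomly allocated
  n_reg <- round(config$p_regular_user * n)
  strata <- sample(rep(c("regular", "new"), c(n_reg, n - n_reg)))
  for (i in seq_len(n)) cohort[[i]]$stratum <- strata[i]
  cohort
}

#' Stratified permuted-block randomization
#'
#' 1:1 within-stratum permuted blocks: block size 10 for the
#' regular-sensor-user stratum and 4 for the new-user stratum.  Within
#' each block, arms are a random permutation of an equal split.
#' Reproducible per seed.
#'
#' @param cohort list of `virtual_participant` (or any list of objects
#'   with `id` and `stratum`).
#' @param seed integer RNG seed.
#' @return data.frame `id`, `stratum`, `arm`.
#' @export
permuted_block_randomize <- function(cohort, seed = 1) {
  set.seed(seed)
  ids <- vapply(cohort, function(p) p$id, numeric(1))
  strata <- vapply(cohort, function(p) p$stratum, character(1))
  out <- data.frame(id = ids, stratum = strata, arm = NA_character_,
                    stringsAsFactors = FALSE)
  for (st in unique(strata)) {
    block <- if (st == "regular") 10L else 4L
    idx <- which(strata == st)
    n_full <- length(idx) %/% block
    rest <- length(idx) %% block
    seq_arms <- unlist(lapply(seq_len(n_full), function(b) {
      sample(rep(c("experimental", "control"), block / 2L))
    }))
    if (rest > 0) {
      # final incomplete block: balanced split (a coin decides the odd slot)
      extra <- rep(c("experimental", "control"), c(ceiling(rest / 2),
                                                   floor(rest / 2)))
      if (rest %% 2L == 1L && runif(1) < 0.5)
        extra <- rep(c("experimental", "control"), c(floor(rest / 2),
                                                     ceiling(rest / 2)))
      seq_arms <- c(seq_arms, sample(extra))
    }
    out$arm[idx] <- seq_arms
  }
  out
}
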