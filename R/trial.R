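# ---- interactive participant simulation ------------------------------------

# Build the decision schedule for `n_days` starting at t0: three meals at
# jittered times with log-normal carb sizes, an evening correction check,
# and the basal-log opportunity. Draws come from the current RNG stream.
draw_day_schedule <- function(day_start, config, snack_rate = config$snack_rate) {
  meals <- names(config$meal_times)
  mt <- config$meal_times + rnorm(3, 0, config$meal_time_sd)
  mt <- pmin(pmax(mt, 300), 1380)
  grams <- rlnorm(3, log(config$meal_grams), config$meal_grams_sdlog)
  n_snack <- stats::rpois(1, snack_rate)
  snack_t <- sort(runif(n_snack, 9 * 60, 22 * 60))
  snack_g <- rlnorm(n_snack, log(config$snack_grams), config$snack_grams_sdlog)
  sched <- data.frame(
    time = day_start + c(mt, snack_t, 21 * 60 + 45, 21 * 60 + 30),
    what = c(rep("meal", 3), rep("snack", n_snack),
             "correction_check", "basal_log"),
    meal = c(meals, rep(NA, n_snack), NA, NA),
    grams = c(grams, snack_g, NA, NA),
    stringsAsFactors = FALSE)
  sched[order(sched$time), , drop = FALSE]
}

#' Simulate a participant's daily life under a therapy
#'
#' Interactive forward simulation: meals perturb true glucose whether or
#' not they are bolused; at each meal the participant uses the bolus
#' calculator with their personal adherence probability (reading the
#' noisy sensor), occasionally overriding the dose; an evening
#' correction check covers hyperglycemia; the basal dose is injected
#' physiologically every day but logged only with the basal-log
#' probability.  Sensor observation uses AR(1) noise on the 15-minute
#' historic grid; decisions read the same noise process.
#'
#' @param participant a `virtual_participant`.
#' @param therapy [therapy_parameters()] in force.
#' @param n_days number of days to simulate.
#' @param t0 start time, minutes since epoch (midnight-aligned).
#' @param config a [cohort_config()].
#' @param state optional model state to continue from.
#' @param carry_log optional prior event log (for insulin-on-board
#'   continuity across weeks).
#' @return list `cgm` (historic + scan records), `log` (events of this
#'   period), `state` (final model state), `truth` (dt-grid trace).
#' @export
simulate_participant_days <- function(participant, therapy, n_days, t0 = 0,
                                      config = cohort_config(), state = NULL,
                                      carry_log = NULL) {
  phys <- participant$physiology
  adh <- participant$adherence
  dt <- config$dt_sim
  if (is.null(state)) state <- fasting_state(phys, therapy$basal_dose)
  params <- phys_param_vec(phys, therapy$basal_dose)
  log <- empty_event_log()
  full_log <- carry_log %||% empty_event_log()

  sched <- do.call(rbind, lapply(seq_len(n_days) - 1L, function(d) {
    draw_day_schedule(t0 + d * 1440, config,
                      snack_rate = adh$snack_rate %||% config$snack_rate)
  }))
  t_end <- t0 + n_days * 1440
  grid15 <- seq(ceiling(t0 / 15) * 15, t_end, by = 15)
  noise15 <- ar1_noise(length(grid15), config$sensor$noise_sd, config$sensor$ar1)
  sensor_at <- function(t, g_true) {
    i <- pmin(pmax(round((t - grid15[1]) / 15) + 1, 1), length(grid15))
    obs <- g_true + noise15[i]
    if (obs < 5) obs <- obs + config$sensor$low_bias
    min(max(obs, SENSOR_RANGE[1]), SENSOR_RANGE[2])
  }

  cuts <- unique(sort(c(t0, sched$time, t_end)))
  truth_t <- numeric(0); truth_g <- numeric(0)
  scans <- data.frame(time = numeric(0), glucose = numeric(0))

  for (i in seq_len(length(cuts) - 1)) {
    t_a <- cuts[i]; t_b <- cuts[i + 1]
    here <- sched[abs(sched$time - t_a) < 1e-9, , drop = FALSE]
    bl <- matrix(numeric(0), 0, 2)
    ml <- matrix(numeric(0), 0, 2)
    for (j in seq_len(nrow(here))) {
      ev <- here[j, ]
      if (ev$what == "snack") {
        # unannounced snack: perturbs true glucose, never bolused or logged
        ml <- rbind(ml, c(ev$time,
                          mean(phys$f) * ev$grams * 1000 / GLUCOSE_MOLAR_MASS))
      } else if (ev$what == "meal") {
        ml <- rbind(ml, c(ev$time,
                          phys$f[[ev$meal]] * ev$grams * 1000 / GLUCOSE_MOLAR_MASS))
        if (runif(1) < adh$p_bolus) {
          gs <- sensor_at(ev$time, state[["G"]])
          carbs_entry <- if (therapy$meal_strategy == "carb_counting")
            round(ev$grams * exp(rnorm(1, adh$carb_bias %||% config$carb_entry_bias,
                                       config$carb_entry_sd))) else NA_real_
          rec <- meal_bolus(therapy, ev$meal, carbs = carbs_entry,
                            glucose = gs, arrow = "stable",
                            events = full_log, now = ev$time)
          delivered <- rec$dose
          reason <- "none"
          if (runif(1) < adh$p_override_dose) {
            delivered <- round_to_increment(rec$dose * runif(1, 0.7, 1.3),
                                            therapy$bolus_increment)
            reason <- sample(OVERRIDE_REASONS[-7], 1)
          }
          log <- add_event(log, ev$time, "meal_bolus", meal = ev$meal,
                           delivered = delivered, carbs = carbs_entry,
                           glucose = gs, arrow = "stable",
                           recommended = rec$dose, override_reason = reason)
          full_log <- add_event(full_log, ev$time, "meal_bolus",
                                meal = ev$meal, delivered = delivered,
                                glucose = gs, recommended = rec$dose)
          scans <- rbind(scans, data.frame(time = ev$time, glucose = gs))
          if (delivered > 0)
            bl <- rbind(bl, c(ev$time,
                              delivered * exp(rnorm(1, 0, config$absorption_sd))))
        }
      } else if (ev$what == "correction_check") {
        if (runif(1) < adh$p_corr) {
          gs <- sensor_at(ev$time, state[["G"]])
          scans <- rbind(scans, data.frame(time = ev$time, glucose = gs))
          if (gs > 10) {
            rec <- correction_bolus(therapy, glucose = gs, arrow = "stable",
                                    events = full_log, now = ev$time)
            if (rec$dose > 0) {
              log <- add_event(log, ev$time, "correction_bolus",
                               delivered = rec$dose, glucose = gs,
                               arrow = "stable", recommended = rec$dose)
              full_log <- add_event(full_log, ev$time, "correction_bolus",
                                    delivered = rec$dose, glucose = gs)
              bl <- rbind(bl, c(ev$time,
                                rec$dose * exp(rnorm(1, 0, config$absorption_sd))))
            }
          }
        }
      } else if (ev$what == "basal_log") {
        if (runif(1) < adh$p_basal) {
          log <- add_event(log, ev$time, "basal",
                           delivered = therapy$basal_dose)
        }
      }
    }
    m <- .sim_gluco_cpp(t_a, t_b, dt, unname(state), params, bl, ml)
    state <- m[nrow(m), -1]
    names(state) <- c("S1", "S2", "I", "X", "Q1", "Q2", "G")
    keep <- if (i < length(cuts) - 1) -nrow(m) else TRUE
    truth_t <- c(truth_t, m[keep, "time"])
    truth_g <- c(truth_g, m[keep, "G"])
  }

  truth <- data.frame(time = truth_t, glucose = truth_g)
  hist_idx <- findInterval(grid15, truth_t)
  hist <- data.frame(
    time = grid15,
    glucose = pmin(pmax(truth_g[hist_idx] + noise15 +
                          ifelse(truth_g[hist_idx] + noise15 < 5,
                                 config$sensor$low_bias, 0),
                        SENSOR_RANGE[1]), SENSOR_RANGE[2]),
    record_type = "historic", stringsAsFactors = FALSE)
  cgm <- rbind(hist,
               if (nrow(scans))
                 data.frame(time = scans$time, glucose = scans$glucose,
                            record_type = "scan", stringsAsFactors = FALSE))
  cgm <- cgm[order(cgm$time), , drop = FALSE]
  list(cgm = cgm, log = log, state = state, truth = truth)
}

#' One realized day of adherence behaviour
#'
#' Convenience wrapper simulating a single day for a participant and
#' returning the realized event log (what the app saw) alongside the
#' sensor trace.  Meals that receive no bolus still perturb the true
#' glucose.
#'
#' @param participant a `virtual_participant`.
#' @param day 0-based day index (sets the clock offset).
#' @param seed integer seed.
#' @param therapy therapy in force (default: the participant's own).
#' @param config a [cohort_config()].
#' @return as [simulate_participant_days()].
#' @export
simulate_adherence <- function(participant, day = 0, seed = 1,
                               therapy = participant$therapy,
                               config = cohort_config()) {
  set.seed(seed)
  simulate_participant_days(participant, therapy, n_days = 1,
                            t0 = day * 1440, config = config)
}

# ---- trial runner ----------------------------------------------------------

#' Trial configuration
#'
#' @param weeks intervention length, weeks.
#' @param p_override_recommendation probability an experimental
#'   participant declines (overrides) a weekly recommendation, keeping
#'   the previous parameters.
#' @param auto_approve auto-approve flagged recommendations (in-silico
#'   stand-in for the clinical review step).
#' @param titration a [titration_control()].
#' @param control_arm_edits if `TRUE`, sparse standard-care parameter
#'   edits are applied to control participants (off by default; the
#'   control arm is static).
#' @return a config list.
#' @export
trial_control <- function(weeks = 12, p_override_recommendation = 0.08,
                          auto_approve = TRUE,
                          titration = titration_control(),
                          control_arm_edits = FALSE) {
  list(weeks = weeks, p_override_recommendation = p_override_recommendation,
       auto_approve = auto_approve, titration = titration,
       control_arm_edits = control_arm_edits)
}

#' Run the two-arm in-silico randomized trial
#'
#' Randomizes the cohort with stratified permuted blocks, then simulates
#' every participant week by week.  Both arms use the bolus calculator
#' with their current parameters; experimental participants additionally
#' receive the weekly titration output, applied the following week upon
#' acknowledgement (a small fraction of recommendations is overridden
#' and not applied).  Control-arm parameters stay fixed.  All weekly
#' metrics, therapy trajectories and the recommendation ledger are
#' recorded.
#'
#' @param cohort list from [generate_cohort()].
#' @param seed integer seed for randomization, adherence and sensor
#'   noise.
#' @param config the [cohort_config()] used to generate the cohort.
#' @param trial a [trial_control()].
#' @return a `trial_result` list: `assignments`, `weekly` (data.frame of
#'   per-participant per-week metrics), `therapy_history`, `ledger`,
#'   `final_therapies`, `seed`.
#' @export
run_trial <- function(cohort, seed = 1, config = cohort_config(),
                      trial = trial_control()) {
  tctl <- trial$titration
  tctl$auto_approve <- trial$auto_approve
  assignments <- permuted_block_randomize(cohort, seed = seed)
  weekly <- list(); ledger <- list(); history <- list()
  final_therapies <- vector("list", length(cohort))

  for (pi in seq_along(cohort)) {
    p <- cohort[[pi]]
    arm <- assignments$arm[assignments$id == p$id]
    set.seed(seed * 1000L + p$id)  # per-participant reproducible stream
    therapy <- p$therapy
    tstate <- titration_state(therapy)
    mstate <- NULL
    carry <- empty_event_log()

    for (wk in seq_len(trial$weeks)) {
      t0 <- (wk - 1L) * 7L * 1440L
      sim <- simulate_participant_days(p, therapy, 7L, t0 = t0,
                                       config = config, state = mstate,
                                       carry_log = carry)
      mstate <- sim$state
      carry <- tail(sim$log, 20L)
      met <- cgm_metrics(sim$cgm, "overall")
      weekly[[length(weekly) + 1L]] <- data.frame(
        id = p$id, arm = arm, week = wk,
        mean_glucose = met$mean_glucose, sd_glucose = met$sd_glucose,
        tir = met$pct_3.9_10, below_3.9 = met$pct_below_3.9,
        above_10 = met$pct_above_10,
        est_hba1c = estimate_hba1c(met$mean_glucose),
        prandial_uses = sum(sim$log$kind == "meal_bolus"),
        basal_logs = sum(sim$log$kind == "basal"),
        correction_uses = sum(sim$log$kind == "correction_bolus"),
        stringsAsFactors = FALSE)
      history[[length(history) + 1L]] <- cbind(
        data.frame(id = p$id, arm = arm, week = wk),
        as.data.frame(as.list(titratable_params(therapy))))

      if (arm == "experimental") {
        wd <- week_data(sim$cgm, sim$log, start = t0, week_index = wk)
        res <- titrate_week(wd, therapy, tstate,
                            constants = patient_physiology(), control = tctl)
        tstate <- res$state
        rec <- res$recommendation
        overridden <- runif(1) < trial$p_override_recommendation
        ledger[[length(ledger) + 1L]] <- data.frame(
          id = p$id, week = wk, flagged = rec$flagged,
          approved = rec$approved, overridden = overridden,
          n_attenuations = length(rec$attenuations),
          max_abs_change = max(abs(rec$changes$relative_change), na.rm = TRUE),
          max_abs_cumulative = max(abs(rec$changes$cumulative_change),
                                   na.rm = TRUE),
          rationale = rec$rationale, stringsAsFactors = FALSE)
        if (!overridden && rec$approved) therapy <- rec$therapy
      }
    }
    final_therapies[[pi]] <- therapy
  }

  structure(list(assignments = assignments,
                 weekly = do.call(rbind, weekly),
                 therapy_history = do.call(rbind, history),
                 ledger = do.call(rbind, ledger),
                 final_therapies = final_therapies,
                 seed = seed),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  n <- nrow(x$assignments)
  cat("In-silico trial:", n, "participants,",
      max(x$weekly$week), "weeks\n")
  cat("  experimental:", sum(x$assignments$arm == "experimental"),
      " control:", sum(x$assignments$arm == "control"), "\n")
  cat("  recommendations:", nrow(x$ledger),
      " flagged:", sum(x$ledger$flagged),
      " overridden:", sum(x$ledger$overridden), "\n")
  invisible(x)
}

#' Per-arm endpoint summary of a trial result
#'
#' Baseline (week 1) and final-week estimated HbA1c per participant,
#' the baseline-adjusted treatment effect, and arm medians of daily
#' prandial calculator use and basal logging.
#'
#' @param result a `trial_result`.
#' @return list `per_participant` (data.frame), `effect`
#'   (from [treatment_effect()]), `usage` (data.frame of arm medians).
#' @export
summarize_trial <- function(result) {
  w <- result$weekly
  last_wk <- max(w$week)
  per <- do.call(rbind, lapply(split(w, w$id), function(d) {
    data.frame(id = d$id[1], arm = d$arm[1],
               baseline_hba1c = d$est_hba1c[d$week == 1],
               final_hba1c = d$est_hba1c[d$week == last_wk],
               prandial_per_day = mean(d$prandial_uses) / 7,
               basal_logs_per_day = mean(d$basal_logs) / 7,
               corrections_per_day = mean(d$correction_uses) / 7,
               stringsAsFactors = FALSE)
  }))
  eff <- treatment_effect(per$baseline_hba1c, per$final_hba1c, per$arm)
  usage <- do.call(rbind, lapply(split(per, per$arm), function(d) {
    data.frame(arm = d$arm[1],
               median_prandial_per_day = median(d$prandial_per_day),
               median_basal_logs_per_day = median(d$basal_logs_per_day),
               median_corrections_per_day = median(d$corrections_per_day))
  }))
  list(per_participant = per, effect = eff, usage = usage)
}
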