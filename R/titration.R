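#' Weekly titration controls
#'
#' Tunable settings of the weekly recommendation engine.
#'
#' @param sigma_cgm residual standard deviation assumed for historic
#'   sensor records in the fit likelihood, mmol/L.
#' @param dt_fit integration step used inside the fit and the therapy
#'   search, minutes.
#' @param maxit quasi-Newton iteration cap for the MAP fit.
#' @param weekly_cap maximum relative parameter movement per week
#'   (insulin scale), fraction.
#' @param review_threshold cumulative-change magnitude beyond which a
#'   recommendation is flagged for clinical review, fraction.
#' @param forgetting inflation factor applied to the posterior sd when it
#'   becomes the next week's prior sd; prevents overconfidence lock-in.
#' @param auto_approve if `TRUE`, flagged recommendations are approved
#'   automatically (in-silico runs); if `FALSE` they are held.
#' @param assumed_carbs named grams assumed per meal type when the diary
#'   carries no carbohydrate entries (fixed-dose users); the fitted
#'   bioavailability absorbs the scale error.
#' @param hypo_threshold sensor reading that counts as hypoglycemia,
#'   mmol/L.
#' @param nadir_threshold postprandial-window nadir below which the
#'   safety rule treats glucose as trending low, mmol/L.
#' @param postprandial_window length of the post-meal window inspected by
#'   the safety rule, minutes.
#' @param search_span multiplicative half-range of the bounded per-meal
#'   therapy search around the previous parameter.
#' @param cost_weights `c(hypo, hyper)` weights of the quadratic band
#'   penalty below 3.9 / above 10 mmol/L.
#' @return a list of control settings.
#' @export
titration_control <- function(sigma_cgm = 0.5, dt_fit = 10, maxit = 30,
                              weekly_cap = 0.20, review_threshold = 0.30,
                              forgetting = 1.25, auto_approve = TRUE,
                              assumed_carbs = c(breakfast = 45, lunch = 60,
                                                dinner = 70),
                              hypo_threshold = 3.9, nadir_threshold = 4.5,
                              postprandial_window = 240,
                              search_span = 2.5,
                              cost_weights = c(hypo = 4, hyper = 1)) {
  list(sigma_cgm = sigma_cgm, dt_fit = dt_fit, maxit = maxit,
       weekly_cap = weekly_cap, review_threshold = review_threshold,
       forgetting = forgetting, auto_approve = auto_approve,
       assumed_carbs = assumed_carbs, hypo_threshold = hypo_threshold,
       nadir_threshold = nadir_threshold,
       postprandial_window = postprandial_window,
       search_span = search_span, cost_weights = cost_weights)
}

FITTED_PARAMS <- c("S_I", "G_b", "k_b", "f_breakfast", "f_lunch", "f_dinner")

#' Log-normal prior over the fitted physiology parameters
#'
#' The weekly fit estimates only the parameters identifiable from sparse
#' flash-monitoring data: insulin sensitivity `S_I`, insulin-free
#' equilibrium glucose `G_b`, the basal plasma-insulin gain `k_b`, and the
#' per-meal bioavailabilities; kinetics are fixed at population values.
#'
#' @param median named medians for `S_I, G_b, k_b, f_breakfast, f_lunch,
#'   f_dinner`.
#' @param sdlog named log-scale standard deviations (same names).
#' @return a `titration_prior` list.
#' @export
titration_prior <- function(median = c(S_I = 8e-4, G_b = 17, k_b = 0.7,
                                       f_breakfast = 0.8, f_lunch = 0.8,
                                       f_dinner = 0.8),
                            sdlog = c(S_I = 0.4, G_b = 0.2, k_b = 0.3,
                                      f_breakfast = 0.3, f_lunch = 0.3,
                                      f_dinner = 0.3)) {
  stopifnot(all(FITTED_PARAMS %in% names(median)),
            all(FITTED_PARAMS %in% names(sdlog)),
            all(median[FITTED_PARAMS] > 0), all(sdlog[FITTED_PARAMS] > 0))
  structure(list(median = median[FITTED_PARAMS], sdlog = sdlog[FITTED_PARAMS]),
            class = "titration_prior")
}

#' Bundle one week of data for the titrator
#'
#' @param cgm CGM trace data.frame (`time`, `glucose`, `record_type`).
#' @param events event log data.frame (see [empty_event_log()]).
#' @param start start of the week, minutes since epoch.
#' @param week_index 1-based week number.
#' @return a `week_data` list.
#' @export
week_data <- function(cgm, events, start, week_index = 1L) {
  if (nrow(cgm) && (min(cgm$time) < start - 1e-6 ||
                    max(cgm$time) > start + 7 * 1440 + 1e-6))
    stop("CGM records must lie within the 7-day week")
  if (nrow(events) && (min(events$time) < start - 1e-6 ||
                       max(events$time) > start + 7 * 1440 + 1e-6))
    stop("events must lie within the 7-day week")
  structure(list(cgm = cgm, events = events, start = start,
                 week_index = week_index), class = "week_data")
}

# embed a fitted-parameter vector phi into a physiology object whose
# kinetics are taken from `constants`
phi_to_physiology <- function(phi, constants) {
  patient_physiology(
    S_I = phi[["S_I"]], S_G = constants$S_G, G_b = phi[["G_b"]],
    p2 = constants$p2, tau_I = constants$tau_I, k_e = constants$k_e,
    V_I = constants$V_I, k_b = phi[["k_b"]], tau_m = constants$tau_m,
    f = c(breakfast = phi[["f_breakfast"]], lunch = phi[["f_lunch"]],
          dinner = phi[["f_dinner"]]),
    V_G = constants$V_G)
}

# Meal schedule the fitter assumes from the diary: logged meal boluses
# (and standalone meal records) with their carbs, or assumed grams for
# fixed-dose users. Bedtime entries use the dinner bioavailability.
diary_meals <- function(events, therapy, control) {
  rows <- events[events$kind %in% c("meal_bolus", "meal"), , drop = FALSE]
  if (!nrow(rows)) {
    return(data.frame(time = numeric(0), grams = numeric(0),
                      meal = character(0), stringsAsFactors = FALSE))
  }
  meal <- ifelse(is.na(rows$meal), "dinner",
                 ifelse(rows$meal == "bedtime", "dinner", rows$meal))
  grams <- rows$carbs
  missing <- is.na(grams)
  grams[missing] <- control$assumed_carbs[meal[missing]]
  data.frame(time = rows$time, grams = grams, meal = meal,
             stringsAsFactors = FALSE)
}

diary_boluses <- function(events) {
  rows <- events[events$kind %in% c("meal_bolus", "correction_bolus") &
                   events$delivered > 0, , drop = FALSE]
  data.frame(time = rows$time, units = rows$delivered)
}

# simulate the week under phi replaying logged doses; returns predicted
# glucose at `at_times` (stripped-down hot path of the MAP objective)
predict_week <- function(phi, constants, therapy, meals, boluses, start,
                         at_times, dt) {
  params <- c(phi[["S_I"]], constants$S_G, phi[["G_b"]], constants$p2,
              constants$tau_I, constants$k_e, constants$V_I, phi[["k_b"]],
              constants$tau_m, constants$V_G, therapy$basal_dose)
  X <- phi[["S_I"]] * phi[["k_b"]] * therapy$basal_dose
  state <- c(0, 0, 0, X, 0, 0,
             constants$S_G * phi[["G_b"]] / (constants$S_G + X))
  f <- c(breakfast = phi[["f_breakfast"]], lunch = phi[["f_lunch"]],
         dinner = phi[["f_dinner"]])
  ml <- if (nrow(meals)) {
    cbind(meals$time, f[meals$meal] * meals$grams * 1000 / GLUCOSE_MOLAR_MASS)
  } else matrix(numeric(0), 0, 2)
  bl <- if (nrow(boluses)) cbind(boluses$time, boluses$units)
        else matrix(numeric(0), 0, 2)
  m <- .sim_gluco_cpp(start, start + 7 * 1440, dt, state, params, bl, ml)
  stats::approx(m[, 1], m[, 8], xout = at_times, rule = 2)$y
}

#' Fit the glucoregulatory model to one week of data
#'
#' Maximum a-posteriori estimation of the fitted physiology parameters
#' from the week's historic sensor records and diary: Gaussian residual
#' likelihood (sd `sigma_cgm`) plus independent log-normal priors,
#' maximized by L-BFGS-B on the log scale from the prior median, with
#' per-parameter posterior standard deviations from the Laplace
#' approximation (numerical Hessian at the MAP).
#'
#' @param week a [week_data()] bundle.
#' @param prior a [titration_prior()].
#' @param therapy the [therapy_parameters()] in force during the week.
#' @param constants a [patient_physiology()] supplying the fixed
#'   kinetics (`S_G, p2, tau_I, k_e, V_I, tau_m, V_G`).
#' @param control a [titration_control()].
#' @return a `posterior_fit` list: `map` (named vector), `post_sd` and
#'   `prior_sd` (log-scale), `r2`, `n_obs`, `converged`.
#' @export
fit_patient_model <- function(week, prior, therapy,
                              constants = patient_physiology(),
                              control = titration_control()) {
  hist <- week$cgm[week$cgm$record_type == "historic", , drop = FALSE]
  n_bolus <- sum(week$events$kind %in% c("meal_bolus", "correction_bolus") &
                   week$events$delivered > 0)
  if (nrow(hist) < 2 || diff(range(hist$time)) < 2 * 1440 || n_bolus < 1)
    stop(structure(class = c("mditrate_degraded_data", "error", "condition"),
                   list(message = "insufficient data: need >= 2 days of CGM and >= 1 logged bolus",
                        call = sys.call())))

  meals <- diary_meals(week$events, therapy, control)
  boluses <- diary_boluses(week$events)
  obs <- hist$glucose
  at <- hist$time
  m <- log(prior$median)
  s <- prior$sdlog

  nlp <- function(psi) {
    phi <- setNames(exp(psi), FITTED_PARAMS)
    pred <- tryCatch(
      predict_week(phi, constants, therapy, meals, boluses, week$start, at,
                   control$dt_fit),
      error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e10)
    0.5 * sum(((obs - pred) / control$sigma_cgm)^2) +
      0.5 * sum(((psi - m) / s)^2)
  }

  lower <- m - 4 * s
  upper <- m + 4 * s
  upper[grep("^f_", FITTED_PARAMS)] <-
    pmin(upper[grep("^f_", FITTED_PARAMS)], 0)  # bioavailability <= 1
  opt <- tryCatch(
    optim(m, nlp, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = control$maxit, factr = 1e9)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10)
    stop(structure(class = c("mditrate_fit_failure", "error", "condition"),
                   list(message = "MAP optimization failed", call = sys.call())))

  psi_hat <- opt$par
  post_sd <- s  # fallback: no information gain
  H <- tryCatch(optimHess(psi_hat, nlp), error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) > 0))
      post_sd <- setNames(sqrt(diag(V)), FITTED_PARAMS)
  }

  phi_hat <- setNames(exp(psi_hat), FITTED_PARAMS)
  pred <- predict_week(phi_hat, constants, therapy, meals, boluses,
                       week$start, at, control$dt_fit)
  ssr <- sum((obs - pred)^2)
  sst <- sum((obs - mean(obs))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else 0

  structure(list(map = phi_hat, post_sd = post_sd,
                 prior_sd = setNames(as.numeric(s), FITTED_PARAMS),
                 r2 = r2, n_obs = length(obs),
                 converged = opt$convergence == 0),
            class = "posterior_fit")
}

# band penalty of the titration cost: heavy quadratic below 3.9 mmol/L,
# quadratic above 10
band_cost <- function(g, weights) {
  mean(weights[["hypo"]] * pmax(0, 3.9 - g)^2 +
         weights[["hyper"]] * pmax(0, g - 10)^2)
}

# Interactive replay of the week's bolused meals under a candidate
# therapy at a given physiology: at each logged meal-bolus time the
# calculator recomputes the dose from the simulated (noise-free) glucose.
replay_week <- function(phys, therapy, meals, start, dt, horizon_days = 7) {
  state <- fasting_state(phys, therapy$basal_dose)
  params <- phys_param_vec(phys, therapy$basal_dose)
  meals <- meals[order(meals$time), , drop = FALSE]
  cuts <- unique(c(start, meals$time, start + horizon_days * 1440))
  cuts <- cuts[cuts >= start & cuts <= start + horizon_days * 1440]
  hist_bolus <- matrix(numeric(0), 0, 2)  # time, units (for IOB)
  ait_min <- therapy$active_insulin_time * 60
  gs <- vector("list", length(cuts) - 1)
  for (i in seq_len(length(cuts) - 1)) {
    t_a <- cuts[i]; t_b <- cuts[i + 1]
    seg_meals <- meals[meals$time >= t_a - 1e-9 & meals$time < t_b - 1e-9, ,
                       drop = FALSE]
    ml <- if (nrow(seg_meals)) {
      cbind(seg_meals$time,
            phys$f[seg_meals$meal] * seg_meals$grams * 1000 / GLUCOSE_MOLAR_MASS)
    } else matrix(numeric(0), 0, 2)
    bl <- matrix(numeric(0), 0, 2)
    for (j in seq_len(nrow(seg_meals))) {
      mrow <- seg_meals[j, ]
      iob <- if (nrow(hist_bolus)) {
        sum(hist_bolus[, 2] *
              pmax(0, 1 - (mrow$time - hist_bolus[, 1]) / ait_min))
      } else 0
      food <- if (therapy$meal_strategy == "carb_counting") {
        ratio_meal <- if (mrow$meal == "bedtime") "dinner" else mrow$meal
        mrow$grams / therapy$carb_ratio[[ratio_meal]]
      } else therapy$fixed_dose[[mrow$meal]]
      dose <- bolus_math(therapy, food, max(0.5, state[[7]]), "stable",
                         iob)$dose
      if (dose > 0) {
        bl <- rbind(bl, c(mrow$time, dose))
        hist_bolus <- rbind(hist_bolus, c(mrow$time, dose))
      }
    }
    m <- .sim_gluco_cpp(t_a, t_b, dt, unname(state), params, bl, ml)
    state <- m[nrow(m), -1]
    gs[[i]] <- m[-nrow(m), 8]
  }
  unlist(gs)
}

#' Unconstrained optimal therapy for the fitted week
#'
#' Derives the therapy that would have given optimal control over the
#' fitted week: the basal dose from the closed-form fasting solution at
#' the MAP physiology, and each prandial parameter from a bounded 1-D
#' search minimizing the weekly band cost (heavily weighted below
#' 3.9 mmol/L, moderately above 10) while replaying the week's bolused
#' meals.
#'
#' @param fit a `posterior_fit` from [fit_patient_model()].
#' @param therapy current [therapy_parameters()].
#' @param week the [week_data()] the fit was computed from.
#' @param constants fixed-kinetics [patient_physiology()].
#' @param control a [titration_control()].
#' @return a [therapy_parameters()] object holding the unconstrained
#'   optimum.
#' @export
optimal_therapy <- function(fit, therapy, week,
                            constants = patient_physiology(),
                            control = titration_control()) {
  phys <- phi_to_physiology(fit$map, constants)
  out <- therapy

  basal_star <- tryCatch(
    steady_state_basal(phys, therapy$glucose_target),
    error = function(e) therapy$basal_dose)
  out$basal_dose <- basal_star

  meals <- diary_meals(week$events, therapy, control)
  # restrict the replay to meals that actually received a bolus
  bolused <- week$events[week$events$kind == "meal_bolus" &
                           week$events$delivered > 0, , drop = FALSE]
  meals <- meals[meals$time %in% bolused$time, , drop = FALSE]
  if (!nrow(meals)) return(out)

  is_cc <- therapy$meal_strategy == "carb_counting"
  for (mt in c("breakfast", "lunch", "dinner")) {
    if (!any(meals$meal == mt)) next
    prev <- if (is_cc) therapy$carb_ratio[[mt]] else therapy$fixed_dose[[mt]]
    if (prev <= 0) next
    objective <- function(v) {
      cand <- out
      if (is_cc) cand$carb_ratio[[mt]] <- v else cand$fixed_dose[[mt]] <- v
      g <- tryCatch(
        replay_week(phys, cand, meals, week$start, control$dt_fit),
        error = function(e) NULL)
      if (is.null(g)) return(1e10)
      # the tiny anchor breaks ties toward the current parameter when the
      # band cost is flat (a well-controlled week has no gradient)
      band_cost(g, control$cost_weights) + 1e-4 * log(v / prev)^2
    }
    res <- tryCatch(
      optimize(objective, lower = prev / control$search_span,
               upper = prev * control$search_span, tol = prev * 0.02),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$objective) && res$objective < 1e10) {
      if (is_cc) out$carb_ratio[[mt]] <- res$minimum
      else out$fixed_dose[[mt]] <- res$minimum
    }
  }
  out
}

# per-titratable-parameter blend weights from a posterior fit:
# w = max(0, R^2) * shrinkage, shrinkage = clip(1 - (post/prior)^2, 0, 1),
# mapped conservatively onto therapy parameters (a therapy parameter
# inherits the weakest shrinkage among the physiology parameters that
# determine it)
blend_weights <- function(fit) {
  shr <- pmin(pmax(1 - (fit$post_sd / fit$prior_sd)^2, 0), 1)
  r2 <- max(0, fit$r2)
  c(basal = r2 * min(shr[c("S_I", "G_b", "k_b")]),
    breakfast = r2 * min(shr[c("S_I", "f_breakfast")]),
    lunch = r2 * min(shr[c("S_I", "f_lunch")]),
    dinner = r2 * min(shr[c("S_I", "f_dinner")]))
}

#' Confidence-weighted blend of optimal and previous therapy
#'
#' Mixes the unconstrained optimum with the previous week's therapy on
#' the log scale, parameter by parameter:
#' `log theta = w*log theta_star + (1-w)*log theta_prev` with
#' `w = max(0, R^2) * clip(1 - (posterior sd/prior sd)^2, 0, 1)`.
#' A week the model cannot explain (R^2 near 0) or that leaves the
#' posterior as wide as the prior moves parameters not at all.
#'
#' @param theta_star optimal [therapy_parameters()].
#' @param theta_prev previous [therapy_parameters()].
#' @param fit `posterior_fit`, or a named weight vector
#'   (`basal`, `breakfast`, `lunch`, `dinner`) used directly.
#' @return blended [therapy_parameters()] with attribute `"weights"`.
#' @export
blend_therapy <- function(theta_star, theta_prev, fit) {
  w <- if (inherits(fit, "posterior_fit")) blend_weights(fit) else fit
  ps <- titratable_params(theta_star)
  pp <- titratable_params(theta_prev)
  blended <- ifelse(ps > 0 & pp > 0,
                    exp(w[names(pp)] * log(pmax(ps[names(pp)], 1e-12)) +
                          (1 - w[names(pp)]) * log(pmax(pp, 1e-12))),
                    pp)
  names(blended) <- names(pp)
  out <- set_titratable_params(theta_prev, blended)
  attr(out, "weights") <- w
  out
}

# hypoglycemia exposure of the week, per meal type and overnight
hypo_exposure <- function(week, control) {
  cgm <- week$cgm
  meals <- week$events[week$events$kind %in% c("meal_bolus", "meal") &
                         !is.na(week$events$meal) &
                         week$events$meal %in% c("breakfast", "lunch", "dinner"),
                       , drop = FALSE]
  per_meal <- sapply(c("breakfast", "lunch", "dinner"), function(mt) {
    times <- meals$time[meals$meal == mt]
    if (!length(times)) return(FALSE)
    any(vapply(times, function(t0) {
      g <- cgm$glucose[cgm$time >= t0 & cgm$time <= t0 + control$postprandial_window]
      length(g) > 0 && (any(g < control$hypo_threshold) ||
                          min(g) < control$nadir_threshold)
    }, logical(1)))
  })
  clock <- cgm$time %% 1440
  overnight <- clock >= 23 * 60 | clock < 7 * 60
  list(meal = per_meal,
       overnight = any(cgm$glucose[overnight] < control$hypo_threshold))
}

#' Safety attenuation of a blended recommendation
#'
#' One-sided rule: on a week where any postprandial window (meal time to
#' +4 h) of a meal type shows a sensor reading below 3.9 mmol/L or a
#' nadir below 4.5 mmol/L, the prandial parameter for that meal may not
#' move toward more insulin than the previous week (carb ratio not
#' decreased, fixed dose not increased); on overnight (23:00-07:00)
#' readings below 3.9 mmol/L the basal dose may not increase.  Decreases
#' always pass.
#'
#' @param theta_blend blended [therapy_parameters()].
#' @param theta_prev previous [therapy_parameters()].
#' @param week the [week_data()].
#' @param control a [titration_control()].
#' @return `theta_blend` with attenuations applied; attribute
#'   `"attenuations"` lists the parameters capped.
#' @export
safety_attenuate <- function(theta_blend, theta_prev, week,
                             control = titration_control()) {
  expo <- hypo_exposure(week, control)
  out <- theta_blend
  applied <- character(0)
  is_cc <- theta_prev$meal_strategy == "carb_counting"
  for (mt in c("breakfast", "lunch", "dinner")) {
    if (!isTRUE(expo$meal[[mt]])) next
    if (is_cc) {
      if (out$carb_ratio[[mt]] < theta_prev$carb_ratio[[mt]]) {
        out$carb_ratio[[mt]] <- theta_prev$carb_ratio[[mt]]
        applied <- c(applied, mt)
      }
    } else {
      if (out$fixed_dose[[mt]] > theta_prev$fixed_dose[[mt]]) {
        out$fixed_dose[[mt]] <- theta_prev$fixed_dose[[mt]]
        applied <- c(applied, mt)
      }
    }
  }
  if (isTRUE(expo$overnight) && out$basal_dose > theta_prev$basal_dose) {
    out$basal_dose <- theta_prev$basal_dose
    applied <- c(applied, "basal")
  }
  attr(out, "attenuations") <- applied
  out
}

# nearest multiple of `step`, exact ties rounding down (conservative)
round_step <- function(value, step) {
  k <- value / step
  lo <- floor(k)
  (lo + as.numeric((k - lo) > 0.5 + 1e-9)) * step
}

#' Finalize a recommendation: cap, round, flag
#'
#' Clips each titratable parameter to within the weekly cap (default
#' 20 percent on the delivered-insulin scale) of its predecessor, rounds
#' basal and fixed doses to the pen increments and carb ratios to
#' 0.1 g/U (rounding toward the previous value so the cap is never
#' breached by rounding), and flags the recommendation for clinical
#' review when any parameter's cumulative change from the reference
#' (baseline or last approved) exceeds the review threshold (default
#' 30 percent).
#'
#' @param theta_safe safety-attenuated [therapy_parameters()].
#' @param theta_prev previous week's [therapy_parameters()].
#' @param theta_reference baseline or last-approved
#'   [therapy_parameters()].
#' @param control a [titration_control()].
#' @return a `recommendation` list: `therapy`, `changes` (per-parameter
#'   data.frame), `flagged`, `approved`, `attenuations`, `weights`,
#'   `rationale`.
#' @export
finalize_recommendation <- function(theta_safe, theta_prev, theta_reference,
                                    control = titration_control()) {
  cap <- control$weekly_cap
  is_cc <- theta_prev$meal_strategy == "carb_counting"
  ps <- titratable_params(theta_safe)
  pp <- titratable_params(theta_prev)
  pr <- titratable_params(theta_reference)
  final <- ps

  for (nm in names(ps)) {
    ratio <- is_cc && nm != "basal"
    u_new <- insulin_scale(ps[[nm]], ratio)
    u_prev <- insulin_scale(pp[[nm]], ratio)
    u_new <- min(max(u_new, u_prev * (1 - cap)), u_prev * (1 + cap))
    v <- if (ratio) 1 / u_new else u_new
    step <- if (nm == "basal") theta_prev$basal_increment
            else if (ratio) 0.1 else theta_prev$bolus_increment
    if (pp[[nm]] <= 0) { final[[nm]] <- pp[[nm]]; next }  # frozen at zero
    v <- round_step(v, step)
    # nearest-rounding may cross the cap by part of a step: walk back
    # toward the previous value until the cap holds; if no grid point
    # fits inside the cap (off-grid predecessor), keep the predecessor
    while (v > 0 &&
           abs(insulin_scale(v, ratio) / u_prev - 1) > cap + 1e-9) {
      nxt <- v + if (v > pp[[nm]]) -step else step
      if ((v - pp[[nm]]) * (nxt - pp[[nm]]) <= 0 && nxt != pp[[nm]]) {
        v <- pp[[nm]]; break
      }
      v <- nxt
    }
    if (v <= 0) v <- pp[[nm]]
    final[[nm]] <- v
  }

  changes <- do.call(rbind, lapply(names(final), function(nm) {
    parameter_change(nm, previous = pp[[nm]], new = final[[nm]],
                     reference = pr[[nm]], is_ratio = is_cc && nm != "basal",
                     review_threshold = control$review_threshold)
  }))
  flagged <- any(changes$flagged)
  therapy <- set_titratable_params(theta_prev, final)
  structure(list(therapy = therapy, changes = changes, flagged = flagged,
                 approved = !flagged || control$auto_approve,
                 attenuations = attr(theta_safe, "attenuations") %||% character(0),
                 weights = attr(theta_safe, "weights"),
                 rationale = "weekly model-based titration"),
            class = "recommendation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recommendation <- function(x, ...) {
  cat("Weekly recommendation (", if (x$flagged) "FLAGGED for review"
      else "unflagged", if (x$approved) ", approved" else ", held", ")\n",
      sep = "")
  print(x$changes, row.names = FALSE)
  if (length(x$attenuations))
    cat("safety attenuations:", paste(x$attenuations, collapse = ", "), "\n")
  invisible(x)
}

no_change_recommendation <- function(therapy, reason) {
  changes <- do.call(rbind, lapply(names(titratable_params(therapy)),
    function(nm) {
      v <- titratable_params(therapy)[[nm]]
      parameter_change(nm, v, v, v,
                       is_ratio = therapy$meal_strategy == "carb_counting" &&
                         nm != "basal")
    }))
  structure(list(therapy = therapy, changes = changes, flagged = FALSE,
                 approved = TRUE, attenuations = character(0),
                 weights = c(basal = 0, breakfast = 0, lunch = 0, dinner = 0),
                 rationale = reason),
            class = "recommendation")
}

#' Run one weekly titration step
#'
#' Full pipeline: MAP fit of the week, derivation of the unconstrained
#' optimal therapy, confidence-weighted blend with the current therapy,
#' safety attenuation, weekly cap, pen rounding and the 30 percent
#' review flag.  The posterior of this week, with its standard
#' deviations inflated by the forgetting factor (and never wider than
#' the initial population prior), becomes the prior of the next week, so
#' information accumulates across the trial.  On insufficient data or a
#' failed fit the therapy is returned unchanged with the failure
#' recorded in the rationale.
#'
#' @param week a [week_data()].
#' @param therapy current [therapy_parameters()].
#' @param state titration state: `list(prior, prior0, reference)` where
#'   `prior` is the current [titration_prior()], `prior0` the initial
#'   one, and `reference` the baseline-or-last-approved
#'   [therapy_parameters()]; pass [titration_state()] at week 1.
#' @param constants fixed-kinetics [patient_physiology()].
#' @param control a [titration_control()].
#' @return `list(recommendation, state)` with the updated state.
#' @export
titrate_week <- function(week, therapy, state,
                         constants = patient_physiology(),
                         control = titration_control()) {
  fit <- tryCatch(
    fit_patient_model(week, state$prior, therapy, constants, control),
    mditrate_degraded_data = function(e) e,
    mditrate_fit_failure = function(e) e)
  if (inherits(fit, "condition")) {
    rec <- no_change_recommendation(therapy,
                                    paste("no change:", conditionMessage(fit)))
    return(list(recommendation = rec, state = state))
  }
  theta_star <- optimal_therapy(fit, therapy, week, constants, control)
  theta_blend <- blend_therapy(theta_star, therapy, fit)
  theta_safe <- safety_attenuate(theta_blend, therapy, week, control)
  attr(theta_safe, "weights") <- attr(theta_blend, "weights")
  rec <- finalize_recommendation(theta_safe, therapy, state$reference, control)

  next_sd <- pmin(fit$post_sd * control$forgetting, state$prior0$sdlog)
  next_sd <- pmax(next_sd, 0.02)
  state$prior <- titration_prior(median = fit$map, sdlog = next_sd)
  # the review reference advances only when a flagged change is approved
  if (rec$flagged && rec$approved) state$reference <- rec$therapy
  list(recommendation = rec, state = state, fit = fit)
}

#' Initial titration state
#'
#' @param therapy baseline [therapy_parameters()] (the initial review
#'   reference).
#' @param prior initial [titration_prior()].
#' @return a state list for [titrate_week()].
#' @export
titration_state <- function(therapy, prior = titration_prior()) {
  list(prior = prior, prior0 = prior, reference = therapy)
}
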