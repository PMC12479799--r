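#' Construct a therapy-parameter set
#'
#' A `therapy_parameters` object holds the titratable prescription of a
#' person on basal-bolus multiple daily injections: the once-daily
#' long-acting basal dose and, per main meal, either a carbohydrate ratio
#' (carb-counting strategy) or a fixed prandial dose (fixed-dose strategy),
#' together with the non-titrated bolus-calculator settings (insulin
#' sensitivity factor, glucose target, active insulin time) and the pen
#' dose increments.  The meal strategy is locked at construction: exactly
#' one of `carb_ratio` / `fixed_dose` is populated.
#'
#' @param basal_dose once-daily basal dose, insulin units (>= 0).
#' @param meal_strategy `"carb_counting"` or `"fixed_dose"`.
#' @param carb_ratio named numeric vector `c(breakfast=, lunch=, dinner=)`,
#'   grams of carbohydrate covered per unit (> 0); required for
#'   carb-counting.
#' @param fixed_dose named numeric vector `c(breakfast=, lunch=, dinner=)`,
#'   units per meal (>= 0); required for fixed-dose.
#' @param isf insulin sensitivity factor, mmol/L glucose drop per unit (> 0).
#' @param glucose_target bolus-calculator glucose target, mmol/L.
#' @param active_insulin_time duration of insulin action for the
#'   insulin-on-board computation, hours (> 0).
#' @param basal_increment basal pen increment, one of 0.5, 1, 2 units.
#' @param bolus_increment bolus pen increment, one of 0.5, 1 units.
#' @return an object of class `therapy_parameters`.
#' @examples
#' therapy_parameters(
#'   basal_dose = 20, meal_strategy = "carb_counting",
#'   carb_ratio = c(breakfast = 10, lunch = 12, dinner = 8),
#'   isf = 2, glucose_target = 6, active_insulin_time = 4)
#' @export
therapy_parameters <- function(basal_dose,
                               meal_strategy = c("carb_counting", "fixed_dose"),
                               carb_ratio = NULL,
                               fixed_dose = NULL,
                               isf,
                               glucose_target = 6.0,
                               active_insulin_time = 4,
                               basal_increment = 1.0,
                               bolus_increment = 0.5) {
  meal_strategy <- match.arg(meal_strategy)
  stopifnot(is.numeric(basal_dose), length(basal_dose) == 1L, basal_dose >= 0,
            is.numeric(isf), isf > 0,
            glucose_target > 0, active_insulin_time > 0)
  if (!basal_increment %in% c(0.5, 1.0, 2.0))
    stop("basal_increment must be one of 0.5, 1.0, 2.0 units")
  if (!bolus_increment %in% c(0.5, 1.0))
    stop("bolus_increment must be one of 0.5, 1.0 units")

  meals <- c("breakfast", "lunch", "dinner")
  if (meal_strategy == "carb_counting") {
    if (is.null(carb_ratio) || !all(meals %in% names(carb_ratio)))
      stop("carb_counting strategy requires carb_ratio for breakfast, lunch, dinner")
    carb_ratio <- carb_ratio[meals]
    if (any(carb_ratio <= 0)) stop("carb ratios must be positive")
    if (!is.null(fixed_dose))
      stop("fixed_dose must be absent under the carb_counting strategy")
  } else {
    if (is.null(fixed_dose) || !all(meals %in% names(fixed_dose)))
      stop("fixed_dose strategy requires fixed_dose for breakfast, lunch, dinner")
    fixed_dose <- fixed_dose[meals]
    if (any(fixed_dose < 0)) stop("fixed doses must be non-negative")
    if (!is.null(carb_ratio))
      stop("carb_ratio must be absent under the fixed_dose strategy")
  }

  structure(list(
    basal_dose = basal_dose,
    meal_strategy = meal_strategy,
    carb_ratio = carb_ratio,
    fixed_dose = fixed_dose,
    isf = isf,
    glucose_target = glucose_target,
    active_insulin_time = active_insulin_time,
    basal_increment = basal_increment,
    bolus_increment = bolus_increment
  ), class = "therapy_parameters")
}

#' @export
print.therapy_parameters <- function(x, ...) {
  cat("Therapy parameters (", x$meal_strategy, ")\n", sep = "")
  cat(sprintf("  basal: %.1f U/day (pen %.1f U)\n", x$basal_dose, x$basal_increment))
  if (x$meal_strategy == "carb_counting") {
    cat(sprintf("  carb ratios (g/U): breakfast %.1f, lunch %.1f, dinner %.1f\n",
                x$carb_ratio["breakfast"], x$carb_ratio["lunch"], x$carb_ratio["dinner"]))
  } else {
    cat(sprintf("  fixed doses (U): breakfast %.1f, lunch %.1f, dinner %.1f\n",
                x$fixed_dose["breakfast"], x$fixed_dose["lunch"], x$fixed_dose["dinner"]))
  }
  cat(sprintf("  ISF %.1f mmol/L/U, target %.1f mmol/L, AIT %.1f h, bolus pen %.1f U\n",
              x$isf, x$glucose_target, x$active_insulin_time, x$bolus_increment))
  invisible(x)
}

#' Round a dose to the pen increment
#'
#' Returns the nearest multiple of `increment`; an exact tie rounds DOWN
#' (hypoglycemia-conservative: when two deliverable doses are equally
#' close, the smaller is dispensed).
#'
#' @param dose non-negative dose, units.
#' @param increment pen increment, one of 0.5, 1, 2 units.
#' @return the rounded dose, units.
#' @examples
#' round_to_increment(6.6, 1.0)  # 7
#' round_to_increment(8.25, 0.5) # 8 (tie rounds down)
#' @export
round_to_increment <- function(dose, increment) {
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be a finite non-negative number")
  if (length(increment) != 1L || !increment %in% c(0.5, 1.0, 2.0))
    stop("increment must be one of 0.5, 1.0, 2.0")
  k <- dose / increment
  lo <- floor(k)
  # tie (fractional part exactly .5, within fp tolerance) -> down
  up <- (k - lo) > 0.5 + 1e-9
  (lo + as.numeric(up)) * increment
}

#' Signed cumulative change of a therapy parameter
#'
#' Fractional change `value/reference - 1` of a parameter relative to its
#' reference (baseline or last clinically approved value).  The clinical
#' review rule flags a recommendation when any parameter's cumulative
#' change exceeds 30 percent in magnitude.
#'
#' @param value current parameter value (same units as `reference`).
#' @param reference strictly positive reference value.
#' @return signed fraction, e.g. `+0.25` for a 25 percent increase.
#' @examples
#' cumulative_change(24, 18)    # +1/3
#' cumulative_change(12.6, 18)  # -0.30
#' @export
cumulative_change <- function(value, reference) {
  if (any(!is.finite(reference)) || any(reference <= 0))
    stop("reference must be strictly positive")
  value / reference - 1
}

# Insulin-delivery scale of one therapy parameter: doses map to themselves,
# carb ratios to the implied dose-per-gram 1/CR, so a +30% insulin change
# flags symmetrically for ratios and fixed doses.
insulin_scale <- function(value, is_ratio) {
  if (is_ratio) 1 / value else value
}

#' Track a parameter change against its reference
#'
#' Builds a `parameter_change` record with the week-over-week relative
#' change and the cumulative change from the reference value, flagging the
#' parameter when the cumulative change exceeds the review threshold.
#' Carbohydrate ratios are compared on the implied dose-per-gram scale
#' (1/ratio) so that "30 percent more insulin" is flagged symmetrically
#' for ratios and doses.
#'
#' @param id parameter identifier string.
#' @param previous previous value (> 0).
#' @param new new value (> 0 for ratios).
#' @param reference reference (baseline or last approved) value.
#' @param is_ratio logical, `TRUE` for carbohydrate ratios.
#' @param review_threshold flag threshold on `|cumulative change|`,
#'   default 0.30.
#' @return a one-row data.frame with columns `parameter`, `previous`,
#'   `new`, `relative_change`, `cumulative_change`, `flagged`.
#' @export
parameter_change <- function(id, previous, new, reference,
                             is_ratio = FALSE, review_threshold = 0.30) {
  prev_s <- insulin_scale(previous, is_ratio)
  new_s <- insulin_scale(new, is_ratio)
  ref_s <- insulin_scale(reference, is_ratio)
  rel <- if (prev_s > 0) cumulative_change(new_s, prev_s)
         else if (new_s == 0) 0 else NA_real_
  cum <- if (ref_s > 0) cumulative_change(new_s, ref_s)
         else if (new_s == 0) 0 else NA_real_
  data.frame(parameter = id, previous = previous, new = new,
             relative_change = rel, cumulative_change = cum,
             flagged = is.finite(cum) && abs(cum) > review_threshold + 1e-9,
             stringsAsFactors = FALSE)
}

# Named vector of the titratable parameters of a therapy, on their native
# scale. Order: basal, then the three prandial parameters.
titratable_params <- function(therapy) {
  if (therapy$meal_strategy == "carb_counting") {
    c(basal = unname(therapy$basal_dose),
      breakfast = unname(therapy$carb_ratio["breakfast"]),
      lunch = unname(therapy$carb_ratio["lunch"]),
      dinner = unname(therapy$carb_ratio["dinner"]))
  } else {
    c(basal = unname(therapy$basal_dose),
      breakfast = unname(therapy$fixed_dose["breakfast"]),
      lunch = unname(therapy$fixed_dose["lunch"]),
      dinner = unname(therapy$fixed_dose["dinner"]))
  }
}

# Rebuild a therapy_parameters object from a titratable-parameter vector.
set_titratable_params <- function(therapy, params) {
  therapy$basal_dose <- unname(params["basal"])
  meals <- c("breakfast", "lunch", "dinner")
  if (therapy$meal_strategy == "carb_counting") {
    therapy$carb_ratio[meals] <- params[meals]
  } else {
    therapy$fixed_dose[meals] <- params[meals]
  }
  therapy
}
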