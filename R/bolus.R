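#' Event logs
#'
#' The dosing and meal diary is a plain data.frame, one row per event,
#' with columns: `id` (integer), `time` (minutes since epoch), `kind`
#' (`"meal_bolus"`, `"correction_bolus"`, `"basal"`, `"meal"`), `meal`
#' (meal type or `NA`), `delivered` (units), `carbs` (grams or `NA`),
#' `glucose` (sensor glucose at entry, mmol/L, or `NA`), `arrow` (trend
#' arrow or `NA`), `recommended` (calculator output, units, or `NA`),
#' `overridden` (logical), `override_reason` (annotation only; never
#' enters any dose computation).
#'
#' @param ... one-row event fields passed to [add_event()].
#' @return an empty event log data.frame.
#' @export
empty_event_log <- function(...) {
  data.frame(id = integer(0), time = numeric(0), kind = character(0),
             meal = character(0), delivered = numeric(0), carbs = numeric(0),
             glucose = numeric(0), arrow = character(0),
             recommended = numeric(0), overridden = logical(0),
             override_reason = character(0), stringsAsFactors = FALSE)
}

EVENT_KINDS <- c("meal_bolus", "correction_bolus", "basal", "meal")
TREND_ARROWS <- c(rising_fast = 2.8, rising = 1.4, stable = 0,
                  falling = -1.4, falling_fast = -2.8)
OVERRIDE_REASONS <- c("dose_higher_than_usual", "exercise", "sick", "stress",
                      "menstrual_cycle", "alcohol", "none")

#' Append an event to a log
#'
#' @param log event log data.frame (see [empty_event_log()]).
#' @param time minutes since epoch.
#' @param kind one of `meal_bolus`, `correction_bolus`, `basal`, `meal`.
#' @param meal meal type annotation or `NA`.
#' @param delivered delivered insulin, units (0 for meal records).
#' @param carbs grams of carbohydrate or `NA`.
#' @param glucose sensor glucose at entry, mmol/L, or `NA`.
#' @param arrow trend arrow or `NA`.
#' @param recommended calculator-recommended dose or `NA`.
#' @param override_reason optional annotation; stored as a note only.
#' @return the log with the new row appended (time-sorted).
#' @export
add_event <- function(log, time, kind, meal = NA_character_, delivered = 0,
                      carbs = NA_real_, glucose = NA_real_,
                      arrow = NA_character_, recommended = NA_real_,
                      override_reason = "none") {
  kind <- match.arg(kind, EVENT_KINDS)
  if (!is.na(arrow) && !arrow %in% names(TREND_ARROWS))
    stop("unknown trend arrow: ", arrow)
  if (!override_reason %in% OVERRIDE_REASONS)
    stop("unknown override reason: ", override_reason)
  if (delivered < 0) stop("delivered dose must be non-negative")
  overridden <- !is.na(recommended) && !isTRUE(all.equal(delivered, recommended))
  row <- data.frame(id = if (nrow(log)) max(log$id) + 1L else 1L,
                    time = time, kind = kind, meal = meal,
                    delivered = delivered, carbs = carbs, glucose = glucose,
                    arrow = arrow, recommended = recommended,
                    overridden = overridden, override_reason = override_reason,
                    stringsAsFactors = FALSE)
  out <- rbind(log, row)
  out[order(out$time), , drop = FALSE]
}

#' Insulin on board
#'
#' Undissipated rapid-acting insulin from previous meal and correction
#' boluses (basal injections are excluded: long-acting insulin is not
#' stacked against).  Each bolus decays over the active insulin time;
#' the default curve is linear (`delivered * max(0, 1 - elapsed/AIT)`),
#' with a single-exponential alternative available.
#'
#' @param events event log data.frame, time-sorted.
#' @param now current time, minutes since epoch.
#' @param active_insulin_time active insulin time, hours (> 0).
#' @param decay `"linear"` (default) or `"exponential"`.  The exponential
#'   curve uses rate `3/AIT` so that about 95 percent of a dose has
#'   dissipated at the end of the active insulin time.
#' @return insulin on board, units (>= 0).
#' @examples
#' log <- add_event(empty_event_log(), 0, "meal_bolus", delivered = 6)
#' insulin_on_board(log, now = 120, active_insulin_time = 4)  # 3 U
#' @export
insulin_on_board <- function(events, now, active_insulin_time,
                             decay = c("linear", "exponential")) {
  decay <- match.arg(decay)
  if (active_insulin_time <= 0) stop("active_insulin_time must be positive")
  if (!nrow(events)) return(0)
  ait_min <- active_insulin_time * 60
  rapid <- events[events$kind %in% c("meal_bolus", "correction_bolus") &
                    events$time <= now, , drop = FALSE]
  if (!nrow(rapid)) return(0)
  elapsed <- now - rapid$time
  frac <- switch(decay,
    linear = pmax(0, 1 - elapsed / ait_min),
    exponential = exp(-3 * elapsed / ait_min))
  sum(rapid$delivered * frac)
}

#' Trend-arrow adjusted glucose
#'
#' Adds a fixed offset to the entered sensor glucose according to the
#' selected trend arrow, anticipating where glucose is heading:
#' rising_fast +2.8, rising +1.4, stable 0, falling -1.4,
#' falling_fast -2.8 mmol/L.  The result is floored at 0.1 mmol/L.
#'
#' @param glucose sensor glucose, mmol/L (> 0).
#' @param arrow one of `rising_fast`, `rising`, `stable`, `falling`,
#'   `falling_fast`.
#' @param offsets optional named replacement offset vector, mmol/L.
#' @return adjusted glucose, mmol/L.
#' @export
trend_adjusted_glucose <- function(glucose, arrow, offsets = TREND_ARROWS) {
  if (!is.numeric(glucose) || any(glucose <= 0)) stop("glucose must be positive")
  if (!arrow %in% names(offsets)) stop("unknown trend arrow: ", arrow)
  max(0.1, glucose + offsets[[arrow]])
}

# Shared dose arithmetic. IOB is subtracted only against the positive part
# of the correction when a food component is present; a standalone
# correction is offset in full.
bolus_math <- function(therapy, food, glucose, arrow, iob,
                       standalone_correction = FALSE) {
  if (is.na(glucose))
    stop("sensor glucose is required: scan before requesting a dose")
  g_adj <- trend_adjusted_glucose(glucose, arrow)
  correction <- (g_adj - therapy$glucose_target) / therapy$isf
  if (standalone_correction) {
    raw <- correction - iob
  } else {
    corr_net <- if (correction > 0) max(0, correction - iob) else correction
    raw <- food + corr_net
  }
  total <- max(0, raw)
  dose <- round_to_increment(total, therapy$bolus_increment)
  list(dose = dose, food = food, correction = correction, iob = iob,
       adjusted_glucose = g_adj, raw = raw)
}

compute_bolus <- function(therapy, food, glucose, arrow, events, now,
                          standalone_correction = FALSE,
                          iob_decay = "linear") {
  iob <- insulin_on_board(events, now, therapy$active_insulin_time,
                          decay = iob_decay)
  bolus_math(therapy, food, glucose, arrow, iob,
             standalone_correction = standalone_correction)
}

#' Meal bolus recommendation
#'
#' Computes the recommended prandial dose: the food component
#' (`carbs / carb_ratio[meal]` under carb counting, or the programmed
#' fixed dose) plus a glucose correction
#' (`(trend-adjusted glucose - target) / ISF`), with insulin on board
#' subtracted only from the positive part of the correction (never from
#' the food component), clipped at zero and rounded to the bolus pen
#' increment.  A negative correction (glucose below target) reduces the
#' food dose.
#'
#' @param therapy a [therapy_parameters()] object.
#' @param meal `"breakfast"`, `"lunch"`, `"dinner"` or `"bedtime"`.
#'   Bedtime has no programmed prandial parameter; its food component is
#'   0 under fixed dosing and carb-covered using the dinner ratio under
#'   carb counting.
#' @param carbs grams of carbohydrate (carb counting only).
#' @param glucose sensor glucose, mmol/L; required.
#' @param arrow trend arrow.
#' @param events event log (for insulin on board).
#' @param now current time, minutes since epoch.
#' @param iob_decay passed to [insulin_on_board()].
#' @return a list with `dose` (units, a multiple of the pen increment)
#'   and the calculation details (`food`, `correction`, `iob`,
#'   `adjusted_glucose`, `raw`).
#' @examples
#' th <- therapy_parameters(20, "carb_counting",
#'   carb_ratio = c(breakfast = 10, lunch = 10, dinner = 10),
#'   isf = 2, glucose_target = 5.5)
#' meal_bolus(th, "dinner", carbs = 60, glucose = 10, arrow = "stable",
#'            events = empty_event_log(), now = 0)
#' @export
meal_bolus <- function(therapy, meal, carbs = NA_real_, glucose, arrow = "stable",
                       events = empty_event_log(), now = 0,
                       iob_decay = "linear") {
  meal <- match.arg(meal, c("breakfast", "lunch", "dinner", "bedtime"))
  if (therapy$meal_strategy == "carb_counting") {
    if (is.na(carbs) || carbs < 0)
      stop("carb_counting strategy requires non-negative carbs")
    ratio_meal <- if (meal == "bedtime") "dinner" else meal
    food <- carbs / therapy$carb_ratio[[ratio_meal]]
  } else {
    if (!is.na(carbs))
      stop("fixed_dose strategy takes no carbohydrate entry")
    food <- if (meal == "bedtime") 0 else therapy$fixed_dose[[meal]]
  }
  compute_bolus(therapy, food, glucose, arrow, events, now,
                standalone_correction = FALSE, iob_decay = iob_decay)
}

#' Correction bolus recommendation
#'
#' Standalone (outside mealtime) correction:
#' `max(0, (trend-adjusted glucose - target)/ISF - IOB)`, rounded to the
#' bolus pen increment.
#'
#' @inheritParams meal_bolus
#' @return as [meal_bolus()].
#' @export
correction_bolus <- function(therapy, glucose, arrow = "stable",
                             events = empty_event_log(), now = 0,
                             iob_decay = "linear") {
  compute_bolus(therapy, food = 0, glucose, arrow, events, now,
                standalone_correction = TRUE, iob_decay = iob_decay)
}

#' Default meal type from clock time
#'
#' Breakfast 05:00-10:59, lunch 11:00-15:59, dinner 16:00-20:59, bedtime
#' otherwise.  The user may override the default in the app; this only
#' sets the preselection.
#'
#' @param clock_minutes minutes since local midnight (0-1439), or a
#'   `"HH:MM"` string.
#' @return meal type string.
#' @examples
#' default_meal_type("07:30")  # breakfast
#' default_meal_type(22 * 60 + 15)  # bedtime
#' @export
default_meal_type <- function(clock_minutes) {
  if (is.character(clock_minutes)) {
    parts <- as.integer(strsplit(clock_minutes, ":", fixed = TRUE)[[1]])
    clock_minutes <- parts[1] * 60 + parts[2]
  }
  m <- clock_minutes %% 1440
  if (m >= 5 * 60 && m < 11 * 60) "breakfast"
  else if (m >= 11 * 60 && m < 16 * 60) "lunch"
  else if (m >= 16 * 60 && m < 21 * 60) "dinner"
  else "bedtime"
}

#' Adherence alerts
#'
#' Two automatic alerts promote engagement: a missed-basal alert when
#' three or more consecutive calendar days have no basal log, and an
#' insufficient-use alert when three or fewer entries were made in the
#' trailing 36 hours.  Alerts clear as soon as their condition no longer
#' holds.
#'
#' @param log event log data.frame.
#' @param now current time, minutes since epoch.
#' @return a list with `missed_basal_streak` (days), `entries_36h`
#'   (count) and `active` (character vector of active alert names).
#' @export
update_alerts <- function(log, now) {
  today <- floor(now / 1440)
  streak <- 0L
  repeat {
    day <- today - 1L - streak          # count back over completed days
    has_basal <- any(log$kind == "basal" &
                       floor(log$time / 1440) == day)
    if (has_basal || streak > 365L) break
    streak <- streak + 1L
  }
  entries <- sum(log$time > now - 36 * 60 & log$time <= now)
  active <- character(0)
  if (streak >= 3L) active <- c(active, "missed_basal")
  if (entries <= 3L) active <- c(active, "insufficient_use")
  list(missed_basal_streak = streak, entries_36h = entries, active = active)
}

#' Delete a diary entry within the correction window
#'
#' Users may delete an erroneous entry within 30 minutes of logging it;
#' later deletion attempts are refused and leave the log unchanged.
#'
#' @param log event log data.frame.
#' @param entry_id id of the entry to delete.
#' @param now current time, minutes since epoch.
#' @return a list with the (possibly unchanged) `log` and `deleted`
#'   (logical).
#' @export
delete_entry <- function(log, entry_id, now) {
  idx <- which(log$id == entry_id)
  if (!length(idx)) stop("entry not found: ", entry_id)
  if (now - log$time[idx] <= 30) {
    list(log = log[-idx, , drop = FALSE], deleted = TRUE)
  } else {
    list(log = log, deleted = FALSE)
  }
}
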