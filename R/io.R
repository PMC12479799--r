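# Timestamps are serialized as ISO-8601 local (naive) strings; internal
# time is minutes since the epoch 1970-01-01 00:00.
time_to_iso <- function(minutes) {
  format(as.POSIXct(minutes * 60, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%S")
}

iso_to_time <- function(iso) {
  t <- as.POSIXct(iso, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (any(is.na(t))) stop("malformed ISO-8601 timestamp: ",
                          iso[which(is.na(t))[1]])
  as.numeric(t) / 60
}

#' Read a CGM export CSV
#'
#' Parses the flash-monitor export dialect: columns
#' `device,serial,timestamp,record_type,glucose_mmol_l`, record_type 0
#' for historic (15-minute) records and 1 for scans, ISO-8601 local
#' timestamps.  Rows are sorted by time; duplicate timestamps collapse
#' keeping the last.  With `unit = "mgdl"` the glucose column is read as
#' mg/dL and converted.
#'
#' @param path file path.
#' @param unit `"mmol"` (default) or `"mgdl"`.
#' @return CGM trace data.frame (`time`, `glucose`, `record_type`).
#' @export
read_cgm_csv <- function(path, unit = c("mmol", "mgdl")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!nrow(raw)) stop("empty CGM file: ", path)
  need <- c("device", "serial", "timestamp", "record_type", "glucose_mmol_l")
  if (!all(need %in% names(raw)))
    stop("CGM file must have columns: ", paste(need, collapse = ", "))
  g <- suppressWarnings(as.numeric(raw$glucose_mmol_l))
  if (any(is.na(g)))
    stop("malformed glucose value at line ", which(is.na(g))[1] + 1L)
  rt <- suppressWarnings(as.integer(raw$record_type))
  if (any(is.na(rt)) || any(!rt %in% 0:1))
    stop("record_type must be 0 (historic) or 1 (scan); bad line ",
         which(is.na(rt) | !rt %in% 0:1)[1] + 1L)
  if (unit == "mgdl") g <- mgdl_to_mmol(g)
  out <- data.frame(time = iso_to_time(raw$timestamp), glucose = g,
                    record_type = ifelse(rt == 0, "historic", "scan"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$time), , drop = FALSE]
  dup <- duplicated(out[, c("time", "record_type")], fromLast = TRUE)
  out[!dup, , drop = FALSE]
}

#' @rdname read_cgm_csv
#' @param trace CGM trace data.frame to write.
#' @param device,serial device annotation columns.
#' @export
write_cgm_csv <- function(trace, path, device = "FreeStyle Libre",
                          serial = "SIM000") {
  df <- data.frame(device = device, serial = serial,
                   timestamp = time_to_iso(trace$time),
                   record_type = ifelse(trace$record_type == "historic", 0L, 1L),
                   glucose_mmol_l = sprintf("%.6g", trace$glucose))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an event log as JSON Lines
#'
#' One JSON object per line mirroring the event-log columns, with
#' ISO-8601 timestamps.  Reading validates the schema: known event
#' kinds, non-negative doses, known override reasons; a violation
#' reports the offending record index.
#'
#' @param path file path.
#' @return event log data.frame.
#' @export
read_event_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  log <- empty_event_log()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) stop("record ", i,
                                             ": malformed JSON"))
    if (is.null(rec$kind) || !rec$kind %in% EVENT_KINDS)
      stop("record ", i, ": unknown event kind")
    if (!is.null(rec$delivered) && rec$delivered < 0)
      stop("record ", i, ": negative dose")
    log <- add_event(log,
                     time = iso_to_time(rec$timestamp),
                     kind = rec$kind,
                     meal = rec$meal %||% NA_character_,
                     delivered = rec$delivered %||% 0,
                     carbs = rec$carbs %||% NA_real_,
                     glucose = rec$glucose %||% NA_real_,
                     arrow = rec$arrow %||% NA_character_,
                     recommended = rec$recommended %||% NA_real_,
                     override_reason = rec$override_reason %||% "none")
  }
  log
}

#' @rdname read_event_log
#' @param log event log data.frame to write.
#' @export
write_event_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log))) {
    rec <- list(timestamp = time_to_iso(log$time[i]), kind = log$kind[i],
                delivered = log$delivered[i])
    if (!is.na(log$meal[i])) rec$meal <- log$meal[i]
    if (!is.na(log$carbs[i])) rec$carbs <- log$carbs[i]
    if (!is.na(log$glucose[i])) rec$glucose <- log$glucose[i]
    if (!is.na(log$arrow[i])) rec$arrow <- log$arrow[i]
    if (!is.na(log$recommended[i])) rec$recommended <- log$recommended[i]
    if (log$override_reason[i] != "none")
      rec$override_reason <- log$override_reason[i]
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read / write therapy parameters as JSON
#'
#' @param path file path.
#' @return a [therapy_parameters()] object.
#' @export
read_therapy_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  known <- c("basal_dose", "meal_strategy", "carb_ratio", "fixed_dose",
             "isf", "glucose_target", "active_insulin_time",
             "basal_increment", "bolus_increment")
  extra <- setdiff(names(x), known)
  if (length(extra)) stop("unknown therapy keys: ", paste(extra, collapse = ", "))
  therapy_parameters(
    basal_dose = x$basal_dose, meal_strategy = x$meal_strategy,
    carb_ratio = if (!is.null(x$carb_ratio)) unlist(x$carb_ratio),
    fixed_dose = if (!is.null(x$fixed_dose)) unlist(x$fixed_dose),
    isf = x$isf, glucose_target = x$glucose_target %||% 6.0,
    active_insulin_time = x$active_insulin_time %||% 4,
    basal_increment = x$basal_increment %||% 1.0,
    bolus_increment = x$bolus_increment %||% 0.5)
}

#' @rdname read_therapy_json
#' @param therapy a [therapy_parameters()] to write.
#' @export
write_therapy_json <- function(therapy, path) {
  x <- unclass(therapy)
  x <- x[!vapply(x, is.null, logical(1))]
  # named vectors serialize as objects, not nameless arrays
  for (nm in c("carb_ratio", "fixed_dose"))
    if (!is.null(x[[nm]])) x[[nm]] <- as.list(x[[nm]])
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a therapy-history CSV
#'
#' Columns `week,basal_u,cr_b,cr_l,cr_d,fd_b,fd_l,fd_d,flagged,approved`;
#' ratio columns are empty for fixed-dose users and vice versa.
#'
#' @param history data.frame with columns `week`, `basal`, `breakfast`,
#'   `lunch`, `dinner`, `strategy`, `flagged`, `approved`.
#' @param path file path.
#' @export
write_therapy_history_csv <- function(history, path) {
  cc <- history$strategy == "carb_counting"
  df <- data.frame(week = history$week,
                   basal_u = history$basal,
                   cr_b = ifelse(cc, history$breakfast, NA),
                   cr_l = ifelse(cc, history$lunch, NA),
                   cr_d = ifelse(cc, history$dinner, NA),
                   fd_b = ifelse(!cc, history$breakfast, NA),
                   fd_l = ifelse(!cc, history$lunch, NA),
                   fd_d = ifelse(!cc, history$dinner, NA),
                   flagged = history$flagged, approved = history$approved)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_therapy_history_csv
#' @export
read_therapy_history_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a run configuration (strict JSON)
#'
#' Nested sections `titration`, `sensor`, `cohort`, `trial`, `seeds`;
#' unknown keys anywhere are rejected so that safety-relevant settings
#' (weekly cap, review threshold) can never be silently misspelled.
#'
#' @param path JSON file path.
#' @return list of config sections merged over package defaults.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known_sections <- c("titration", "sensor", "cohort", "trial", "seeds")
  extra <- setdiff(names(x), known_sections)
  if (length(extra)) stop("unknown config sections: ",
                          paste(extra, collapse = ", "))
  check_keys <- function(section, allowed) {
    if (is.null(x[[section]])) return(invisible())
    bad <- setdiff(names(x[[section]]), allowed)
    if (length(bad)) stop("unknown keys in [", section, "]: ",
                          paste(bad, collapse = ", "))
  }
  check_keys("titration", names(formals(titration_control)))
  check_keys("sensor", names(formals(sensor_model)))
  check_keys("cohort", names(formals(cohort_config)))
  check_keys("trial", names(formals(trial_control)))
  tit <- do.call(titration_control, as.list(x$titration %||% list()))
  sen <- do.call(sensor_model, as.list(x$sensor %||% list()))
  coh <- do.call(cohort_config, c(as.list(x$cohort %||% list()),
                                  list(sensor = sen)))
  tri <- do.call(trial_control, c(as.list(x$trial %||% list()),
                                  list(titration = tit)))
  list(titration = tit, sensor = sen, cohort = coh, trial = tri,
       seeds = x$seeds %||% list())
}
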