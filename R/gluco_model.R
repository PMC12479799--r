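#' Virtual-patient physiology
#'
#' Parameters of the glucoregulatory model used both as the virtual
#' patient in simulations and as the fitting model inside the weekly
#' titrator.  The model is a Bergman-style minimal model (glucose G with
#' effectiveness `S_G` and remote insulin action X), a two-compartment
#' subcutaneous rapid-insulin chain (S1 -> S2 -> plasma I), a
#' two-compartment gut absorption chain (Q1 -> Q2), and a once-daily
#' long-acting basal represented as a constant plasma insulin
#' contribution `k_b * B` (appropriate for degludec/glargine at steady
#' state).
#'
#' @param S_I insulin sensitivity, 1/min per (mU/L).
#' @param S_G glucose effectiveness, 1/min.
#' @param G_b insulin-free equilibrium glucose, mmol/L.
#' @param p2 remote-insulin activation rate, 1/min.
#' @param tau_I subcutaneous rapid-insulin time constant, min.
#' @param k_e plasma insulin elimination rate, 1/min.
#' @param V_I insulin distribution volume, L.
#' @param k_b plasma insulin contribution per basal unit/day,
#'   (mU/L) per (U/day).
#' @param tau_m meal absorption time constant, min.
#' @param f named bioavailability fractions in (0, 1] per meal type
#'   (`breakfast`, `lunch`, `dinner`).
#' @param V_G glucose distribution volume, L.
#' @return object of class `patient_physiology`.
#' @export
patient_physiology <- function(S_I = 8e-4, S_G = 0.01, G_b = 15, p2 = 0.02,
                               tau_I = 55, k_e = 0.14, V_I = 9, k_b = 0.7,
                               tau_m = 40,
                               f = c(breakfast = 0.8, lunch = 0.8, dinner = 0.8),
                               V_G = 12) {
  vals <- c(S_I = S_I, S_G = S_G, G_b = G_b, p2 = p2, tau_I = tau_I,
            k_e = k_e, V_I = V_I, k_b = k_b, tau_m = tau_m, V_G = V_G)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all physiology parameters must be positive and finite")
  meals <- c("breakfast", "lunch", "dinner")
  if (!all(meals %in% names(f)) || any(f <= 0) || any(f > 1))
    stop("f must give bioavailabilities in (0, 1] for breakfast, lunch, dinner")
  structure(c(as.list(vals), list(f = f[meals])), class = "patient_physiology")
}

# parameter vector for the compiled stepper
phys_param_vec <- function(phys, basal_dose) {
  c(phys$S_I, phys$S_G, phys$G_b, phys$p2, phys$tau_I, phys$k_e,
    phys$V_I, phys$k_b, phys$tau_m, phys$V_G, basal_dose)
}

#' Fasting steady state of the model
#'
#' Closed-form equilibrium with no meals or boluses under constant basal
#' `B`: `X_ss = S_I*k_b*B`, `G_ss = S_G*G_b / (S_G + X_ss)`.
#'
#' @param phys a [patient_physiology()] object.
#' @param basal_dose basal dose, units/day.
#' @return named state vector `c(S1, S2, I, X, Q1, Q2, G)`.
#' @export
fasting_state <- function(phys, basal_dose) {
  X <- phys$S_I * phys$k_b * basal_dose
  G <- phys$S_G * phys$G_b / (phys$S_G + X)
  c(S1 = 0, S2 = 0, I = 0, X = X, Q1 = 0, Q2 = 0, G = G)
}

#' Closed-form basal dose for a fasting glucose target
#'
#' Solves the fasting equilibrium for the once-daily basal dose that
#' holds glucose at `target`: `B = S_G*(G_b - target) / (S_I*k_b*target)`.
#' Serves as the analytic oracle for basal titration.
#'
#' @param phys a [patient_physiology()] object.
#' @param target fasting glucose target, mmol/L; must satisfy
#'   `0 < target < G_b`.
#' @return basal dose, units/day.
#' @export
steady_state_basal <- function(phys, target) {
  if (target <= 0 || target >= phys$G_b)
    stop("no solution: target must lie in (0, G_b)")
  phys$S_G * (phys$G_b - target) / (phys$S_I * phys$k_b * target)
}

#' Simulate the glucoregulatory model
#'
#' Integrates the model on a fixed grid with rapid boluses as impulses
#' into the subcutaneous chain and meals as impulses into the gut chain.
#' Per-meal bioavailability is applied at ingestion: a meal of `g` grams
#' of type `m` injects `f[m] * g * 1000/180.16` mmol into Q1.
#'
#' @param phys a [patient_physiology()] object.
#' @param basal_dose once-daily basal dose, units/day (constant plasma
#'   contribution).
#' @param boluses data.frame with columns `time` (min) and `units`, or
#'   NULL.
#' @param meals data.frame with columns `time` (min), `grams`, `meal`
#'   (type), or NULL.
#' @param horizon_days simulation length, days (from `t0`).
#' @param t0 start time, minutes since epoch.
#' @param dt integration step, minutes (default 1).
#' @param state initial state (default: fasting steady state at
#'   `basal_dose`).
#' @return data.frame with columns `time` and `glucose`; full state
#'   matrix in attribute `"states"`.
#' @examples
#' p <- patient_physiology()
#' tr <- simulate_glucose(p, basal_dose = steady_state_basal(p, 6),
#'                        horizon_days = 1)
#' range(tr$glucose)
#' @export
simulate_glucose <- function(phys, basal_dose, boluses = NULL, meals = NULL,
                             horizon_days = 1, t0 = 0, dt = 1, state = NULL) {
  stopifnot(horizon_days > 0, basal_dose >= 0)
  if (is.null(state)) state <- fasting_state(phys, basal_dose)
  bol <- if (is.null(boluses) || !nrow(boluses)) {
    matrix(numeric(0), 0, 2)
  } else cbind(boluses$time, boluses$units)
  ml <- if (is.null(meals) || !nrow(meals)) {
    matrix(numeric(0), 0, 2)
  } else {
    cbind(meals$time,
          phys$f[as.character(meals$meal)] * meals$grams * 1000 / GLUCOSE_MOLAR_MASS)
  }
  m <- .sim_gluco_cpp(t0, t0 + horizon_days * 1440, dt,
                      unname(state), phys_param_vec(phys, basal_dose), bol, ml)
  out <- data.frame(time = m[, "time"], glucose = m[, "G"])
  attr(out, "states") <- m
  out
}

#' Intermittently-scanned sensor model
#'
#' @param noise_sd marginal noise standard deviation, mmol/L.
#' @param ar1 lag-1 autocorrelation of the noise on the 15-min record
#'   grid (0 = white).
#' @param low_bias additive bias (mmol/L) applied to readings below
#'   5 mmol/L; negative values emulate the tendency of first-generation
#'   flash sensors to over-read hypoglycemia exposure.
#' @return a list of sensor parameters.
#' @export
sensor_model <- function(noise_sd = 0.4, ar1 = 0.7, low_bias = 0) {
  stopifnot(noise_sd >= 0, ar1 >= 0, ar1 < 1)
  list(noise_sd = noise_sd, ar1 = ar1, low_bias = low_bias)
}

SENSOR_RANGE <- c(2.2, 27.8)

# AR(1) noise with given marginal sd at n points
ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(numeric(n))
  e <- rnorm(n, 0, sd * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd)
  for (i in seq_len(n - 1)) x[i + 1] <- rho * x[i] + e[i + 1]
  x
}

#' Observe a glucose trace through the sensor model
#'
#' Produces a CGM trace data.frame (`time`, `glucose`, `record_type`)
#' from a true glucose trace: historic records on a regular 15-minute
#' grid plus scan records at the requested times, with AR(1) correlated
#' noise of the given marginal standard deviation, the optional low-range
#' bias below 5 mmol/L, and clamping to the sensor reporting range
#' [2.2, 27.8] mmol/L.  Deterministic for a fixed seed.
#'
#' @param trace data.frame `time`, `glucose` (true values, regular grid).
#' @param sensor a [sensor_model()].
#' @param scan_times numeric vector of scan times (minutes), within the
#'   trace span.
#' @param seed integer RNG seed.
#' @return CGM trace data.frame.
#' @export
observe_cgm <- function(trace, sensor = sensor_model(), scan_times = numeric(0),
                        seed = 1) {
  stopifnot(nrow(trace) >= 2)
  if (length(scan_times) &&
      (min(scan_times) < min(trace$time) || max(scan_times) > max(trace$time)))
    stop("scan times must lie within the trace span")
  grid <- seq(ceiling(min(trace$time) / 15) * 15, max(trace$time), by = 15)
  times <- c(grid, scan_times)
  truth <- stats::approx(trace$time, trace$glucose, xout = times)$y
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(seed)
  noise_grid <- ar1_noise(length(grid), sensor$noise_sd, sensor$ar1)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  # scans share the noise of the nearest historic grid point (same sensor)
  noise <- c(noise_grid,
             if (length(scan_times)) {
               noise_grid[pmin(pmax(round((scan_times - grid[1]) / 15) + 1, 1),
                               length(grid))]
             })
  obs <- truth + noise
  obs <- ifelse(obs < 5, obs + sensor$low_bias, obs)
  obs <- pmin(pmax(obs, SENSOR_RANGE[1]), SENSOR_RANGE[2])
  out <- data.frame(time = times, glucose = obs,
                    record_type = rep(c("historic", "scan"),
                                      c(length(grid), length(scan_times))))
  out[order(out$time), , drop = FALSE]
}
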