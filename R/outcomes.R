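GLYCEMIC_PERIODS <- c("overall", "daytime", "overnight")

#' CGM glycemic metrics
#'
#' Percent time in the standard consensus glucose bands, mean and
#' standard deviation of sensor glucose, computed over historic records
#' only (scans duplicate the same sensor signal).  "In range" bands are
#' closed intervals; "above"/"below" bands are strict.  Daytime is
#' 07:00-23:00 and overnight 23:00-07:00 by wall clock.
#'
#' @param trace CGM trace data.frame (`time` minutes since epoch,
#'   `glucose` mmol/L, `record_type`).
#' @param period `"overall"`, `"daytime"` or `"overnight"`.
#' @return a list of class `glycemic_metrics`: percentages
#'   `pct_3.9_10`, `pct_3.9_7.8`, `pct_below_3.9`, `pct_below_3.0`,
#'   `pct_above_7.8`, `pct_above_10`, `pct_above_13.9`,
#'   `pct_above_16.7`, plus `mean_glucose`, `sd_glucose`, `n`, `period`.
#' @export
cgm_metrics <- function(trace, period = c("overall", "daytime", "overnight")) {
  period <- match.arg(period)
  g <- trace$glucose[trace$record_type == "historic"]
  clock <- trace$time[trace$record_type == "historic"] %% 1440
  keep <- switch(period,
    overall = rep(TRUE, length(g)),
    daytime = clock >= 7 * 60 & clock < 23 * 60,
    overnight = clock >= 23 * 60 | clock < 7 * 60)
  g <- g[keep]
  if (!length(g))
    stop("no historic records in the requested period")
  pct <- function(x) 100 * mean(x)
  structure(list(
    pct_3.9_10 = pct(g >= 3.9 & g <= 10),
    pct_3.9_7.8 = pct(g >= 3.9 & g <= 7.8),
    pct_below_3.9 = pct(g < 3.9),
    pct_below_3.0 = pct(g < 3.0),
    pct_above_7.8 = pct(g > 7.8),
    pct_above_10 = pct(g > 10),
    pct_above_13.9 = pct(g > 13.9),
    pct_above_16.7 = pct(g > 16.7),
    mean_glucose = mean(g),
    sd_glucose = if (length(g) > 1) sd(g) else 0,
    n = length(g), period = period), class = "glycemic_metrics")
}

#' Estimated HbA1c (glucose management indicator)
#'
#' Regression-based HbA1c estimate from mean sensor glucose:
#' `GMI (%) = 3.31 + 0.02392 * mean glucose (mg/dL)`.  An in-silico
#' surrogate for laboratory HbA1c; it is not a claim about assay values.
#'
#' @param mean_glucose mean glucose, mmol/L (> 0).
#' @return estimated HbA1c, percent.
#' @examples
#' estimate_hba1c(8.6)   # ~7.0
#' estimate_hba1c(12.3)  # ~8.6
#' @export
estimate_hba1c <- function(mean_glucose) {
  if (any(mean_glucose <= 0)) stop("mean glucose must be positive")
  3.31 + 0.02392 * mean_glucose * MGDL_PER_MMOL
}

#' Baseline-adjusted treatment effect
#'
#' Analysis of covariance of the change from baseline on arm plus
#' baseline value (with a single post-baseline measurement the linear
#' mixed model for the endpoint reduces to this form).  The effect is
#' the experimental-minus-control adjusted difference with its Wald 95
#' percent confidence interval and a two-sided p value.
#'
#' @param baseline per-subject baseline values.
#' @param final per-subject final values (same order).
#' @param arm factor/character vector, `"control"` or `"experimental"`.
#' @return list `effect`, `ci` (length 2), `p`, `n`.
#' @export
treatment_effect <- function(baseline, final, arm) {
  stopifnot(length(baseline) == length(final), length(arm) == length(final))
  arm <- factor(arm, levels = c("control", "experimental"))
  if (any(table(arm) < 2)) stop("need at least 2 subjects per arm")
  change <- final - baseline
  fit <- lm(change ~ arm + baseline)
  est <- coef(fit)[["armexperimental"]]
  se <- sqrt(vcov(fit)["armexperimental", "armexperimental"])
  df <- fit$df.residual
  tstat <- est / se
  list(effect = est,
       ci = est + c(-1, 1) * qt(0.975, df) * se,
       p = 2 * stats::pt(-abs(tstat), df),
       n = length(change))
}

#' Two-proportion comparison
#'
#' Compares `k1/n1` against `k2/n2` with either the pooled two-proportion
#' chi-squared test (no continuity correction) or Fisher's exact test
#' (two-sided, summing hypergeometric tables no more probable than the
#' observed one).  The difference in proportions carries a Wald 95
#' percent confidence interval.
#'
#' @param k1,n1 events and total, group 1.
#' @param k2,n2 events and total, group 2.
#' @param method `"chi_squared"` or `"fisher"`.
#' @return list `difference`, `ci`, `p`, `method`.
#' @examples
#' proportion_test(5, 42, 0, 42, method = "fisher")$p   # 0.055
#' @export
proportion_test <- function(k1, n1, k2, n2,
                            method = c("chi_squared", "fisher")) {
  method <- match.arg(method)
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  d <- p1 - p2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  ci <- d + c(-1, 1) * qnorm(0.975) * se
  p <- if (method == "chi_squared") {
    prop.test(c(k1, k2), c(n1, n2), correct = FALSE)$p.value
  } else {
    fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE))$p.value
  }
  list(difference = d, ci = ci, p = p, method = method)
}

#' Per-arm sample size for a two-sample t-test
#'
#' Smallest integer group size giving the target power for a two-sided
#' two-sample t-test at significance level `alpha`, iterating on the
#' t-distribution degrees of freedom.
#'
#' @param sd common standard deviation of the endpoint.
#' @param delta between-group difference to detect.
#' @param power target power.
#' @param alpha two-sided significance level.
#' @return integer n per arm.
#' @examples
#' sample_size_two_sample_t(0.8, 0.5, 0.80, 0.05)  # 42
#' @export
sample_size_two_sample_t <- function(sd, delta, power = 0.80, alpha = 0.05) {
  stopifnot(sd > 0, delta > 0, power > 0, power < 1, alpha > 0, alpha < 1)
  as.integer(ceiling(power.t.test(delta = delta, sd = sd, power = power,
                                  sig.level = alpha,
                                  type = "two.sample")$n))
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk tests each group at alpha 0.05; if both look normal an
#' independent two-sample (Welch) t-test is used, otherwise the Wilcoxon
#' rank-sum test.  Two-sided.
#'
#' @param x,y numeric samples (>= 3 each).
#' @return list `statistic`, `p`, `test` (`"t"` or `"wilcoxon"`).
#' @export
two_group_compare <- function(x, y) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  normal <- shapiro.test(x)$p.value > 0.05 && shapiro.test(y)$p.value > 0.05
  if (normal) {
    ht <- t.test(x, y)
    list(statistic = unname(ht$statistic), p = ht$p.value, test = "t")
  } else {
    ht <- wilcox.test(x, y, exact = FALSE)
    list(statistic = unname(ht$statistic), p = ht$p.value, test = "wilcoxon")
  }
}
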