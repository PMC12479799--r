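test_that("glycemic metrics use the stated band boundaries", {
  m <- cgm_metrics(flat_trace(6.5))
  expect_equal(m$pct_3.9_10, 100)
  expect_equal(m$pct_below_3.9, 0)
  expect_equal(m$pct_above_10, 0)
  expect_equal(m$sd_glucose, 0)
  # constructed half/half split
  tr <- flat_trace(6.5, days = 1)[1:96, ]
  tr$glucose <- rep(c(3.0, 12.0), length.out = 96)
  m2 <- cgm_metrics(tr)
  expect_equal(m2$pct_below_3.9, 50)
  expect_equal(m2$pct_above_10, 50)
  expect_equal(m2$pct_3.9_10, 0)
  # boundary values are in range ("in" closed, ">" and "<" strict)
  tr3 <- flat_trace(6, days = 1)
  tr3$glucose <- rep(c(3.9, 10), length.out = nrow(tr3))
  m3 <- cgm_metrics(tr3)
  expect_equal(m3$pct_3.9_10, 100)
  expect_equal(m3$pct_above_10, 0)
  expect_equal(m3$pct_below_3.9, 0)
})

test_that("period filters follow the wall clock and error when empty", {
  tr <- flat_trace(6, days = 2)
  night <- tr$time %% 1440 >= 23 * 60 | tr$time %% 1440 < 7 * 60
  tr$glucose[night] <- 12
  expect_equal(cgm_metrics(tr, "overnight")$pct_above_10, 100)
  expect_equal(cgm_metrics(tr, "daytime")$pct_above_10, 0)
  only_night <- tr[night, ]
  expect_error(cgm_metrics(only_night, "daytime"), "no historic")
  # scans never enter metrics
  tr_s <- rbind(tr, data.frame(time = 100, glucose = 25, record_type = "scan"))
  expect_equal(cgm_metrics(tr_s, "overnight")$pct_above_10, 100)
})

test_that("metric normalization identities hold on random traces", {
  set.seed(21)
  for (i in 1:20) {
    tr <- flat_trace(6, days = 3)
    tr$glucose <- exp(rnorm(nrow(tr), log(runif(1, 1.6, 2.6)), 0.35))
    m <- cgm_metrics(tr)
    expect_equal(m$pct_below_3.9 + m$pct_3.9_10 + m$pct_above_10, 100,
                 tolerance = 1e-9)
    expect_lte(m$pct_below_3.0, m$pct_below_3.9)
    expect_lte(m$pct_above_16.7, m$pct_above_13.9)
    expect_lte(m$pct_above_13.9, m$pct_above_10)
    expect_lte(m$pct_above_10, m$pct_above_7.8)
    expect_equal(m$pct_3.9_7.8 + m$pct_below_3.9 + m$pct_above_7.8, 100,
                 tolerance = 1e-9)
  }
})

test_that("the glucose management indicator matches its published regression", {
  expect_equal(estimate_hba1c(8.6), 7.02, tolerance = 0.005)
  expect_equal(estimate_hba1c(12.3), 8.61, tolerance = 0.005)
  expect_gt(estimate_hba1c(12), estimate_hba1c(9))
  expect_error(estimate_hba1c(0))
})

test_that("the baseline-adjusted treatment effect behaves as an ANCOVA", {
  set.seed(31)
  # identical arms: effect 0, p ~ 1
  base <- rep(rnorm(20, 8.6, 1), 2)
  fin <- base + rep(rnorm(20, -0.3, 0.5), 2)  # identical subjects per arm
  arm <- rep(c("control", "experimental"), each = 20)
  te0 <- treatment_effect(base, fin, arm)
  expect_equal(te0$effect, 0, tolerance = 1e-9)
  expect_gt(te0$p, 0.99)
  # baseline-balanced design: coefficient equals the difference in means
  base2 <- rep(rnorm(25, 8.5, 0.9), 2)
  change <- c(rnorm(25, -0.1, 0.4), rnorm(25, -0.5, 0.4))
  arm2 <- rep(c("control", "experimental"), each = 25)
  te <- treatment_effect(base2, base2 + change, arm2)
  expect_equal(te$effect,
               mean(change[26:50]) - mean(change[1:25]), tolerance = 1e-6)
  expect_error(treatment_effect(1:3, 1:3, c("control", "control", "control")))
})

test_that("the treatment effect recovers a known shift in large samples", {
  set.seed(32)
  n <- 2000
  base <- rnorm(2 * n, 8.6, 1.0)
  arm <- rep(c("control", "experimental"), each = n)
  fin <- base + rnorm(2 * n, 0, 0.8) + ifelse(arm == "experimental", -0.4, 0)
  te <- treatment_effect(base, fin, arm)
  expect_equal(te$effect, -0.4, tolerance = 0.06)
  expect_lt(te$ci[1], te$effect)
  expect_gt(te$ci[2], te$effect)
})

test_that("treatment_effect holds its type-I error under the null", {
  set.seed(33)
  reps <- 2000
  hits <- 0L
  for (i in seq_len(reps)) {
    base <- rnorm(84, 8.6, 1.0)
    fin <- base + rnorm(84, -0.2, 0.8)
    arm <- rep(c("control", "experimental"), each = 42)
    if (treatment_effect(base, fin, arm)$p < 0.05) hits <- hits + 1L
  }
  expect_equal(hits / reps, 0.05, tolerance = 0.011)
})

test_that("proportion tests reproduce the trial's printed p values", {
  expect_equal(proportion_test(5, 42, 0, 42, "fisher")$p, 0.055,
               tolerance = 0.01)
  expect_equal(proportion_test(8, 42, 7, 42, "fisher")$p, 1.0,
               tolerance = 1e-6)
  expect_equal(proportion_test(22, 42, 13, 42, "chi_squared")$p, 0.046,
               tolerance = 0.01)
  expect_error(proportion_test(2, 0, 1, 5))
})

test_that("fisher matches brute-force hypergeometric enumeration", {
  brute_fisher <- function(k1, n1, k2, n2) {
    m <- k1 + k2
    xs <- max(0, m - n2):min(n1, m)
    probs <- dhyper(xs, n1, n2, m)
    p_obs <- dhyper(k1, n1, n2, m)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  cases <- list(c(5, 42, 0, 42), c(8, 42, 7, 42), c(3, 10, 7, 12),
                c(0, 5, 5, 5), c(22, 42, 13, 42), c(1, 30, 4, 25))
  for (cs in cases) {
    expect_equal(proportion_test(cs[1], cs[2], cs[3], cs[4], "fisher")$p,
                 brute_fisher(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-7)
  }
})

test_that("the chi-squared statistic equals the pooled two-proportion z^2", {
  cases <- list(c(22, 42, 13, 42), c(12, 40, 22, 45), c(30, 60, 20, 55))
  for (cs in cases) {
    k1 <- cs[1]; n1 <- cs[2]; k2 <- cs[3]; n2 <- cs[4]
    p_pool <- (k1 + k2) / (n1 + n2)
    z <- (k1 / n1 - k2 / n2) /
      sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
    expect_equal(proportion_test(k1, n1, k2, n2, "chi_squared")$p,
                 2 * pnorm(-abs(z)), tolerance = 1e-9)
  }
})

test_that("the power calculation reproduces the trial's sample size", {
  expect_identical(sample_size_two_sample_t(0.8, 0.5, 0.80, 0.05), 42L)
  # normal-approximation oracle: 2*sd^2*(z_{.975}+z_{.8})^2/delta^2
  n_norm <- ceiling(2 * 0.8^2 * (qnorm(0.975) + qnorm(0.8))^2 / 0.5^2)
  expect_identical(n_norm, 41)  # t correction adds one
  # monotone decreasing in the detectable difference
  ns <- vapply(c(0.3, 0.5, 0.8, 1.5, 3), function(d)
    sample_size_two_sample_t(0.8, d), integer(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("the normality gate picks the t-test or the rank-sum test", {
  set.seed(41)
  g1 <- rnorm(200); g2 <- rnorm(200, 0.1)
  expect_equal(two_group_compare(g1, g2)$test, "t")
  e1 <- rexp(200); e2 <- rexp(200, 0.8)
  expect_equal(two_group_compare(e1, e2)$test, "wilcoxon")
  x <- rnorm(50)
  expect_gt(two_group_compare(x, x)$p, 0.99)
})
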