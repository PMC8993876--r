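test_that("product-limit estimates match hand-worked computation", {
  # times 2, 4+, 5, 7+, 9: S = 4/5, then 4/5*2/3, then 0
  fit <- km_estimate(c(2, 4, 5, 7, 9), c(1, 0, 1, 0, 1))
  ev <- fit$n_event > 0
  expect_equal(fit$time[ev], c(2, 5, 9))
  expect_equal(fit$surv[ev], c(4 / 5, 4 / 5 * 2 / 3, 0), tolerance = 1e-12)
  expect_equal(fit$n_risk[ev], c(5, 3, 1))
  # smallest time where survival drops to 0.5 or below: S(5) = 0.53, S(9) = 0
  expect_equal(fit$median_os, 9)

  # no censoring: empirical median; survival equals 1 - ECDF
  fit <- km_estimate(1:5, rep(1, 5))
  expect_equal(fit$median_os, 3)
  expect_equal(fit$surv, 1 - ecdf(1:5)(fit$time), tolerance = 1e-12)

  # all censored: median never reached
  fit <- km_estimate(c(10, 20, 30), c(0, 0, 0))
  expect_false(fit$median_reached)
  expect_true(is.na(fit$median_os))

  expect_error(km_estimate(numeric(), integer()), "empty")
  expect_error(km_estimate(c(1, -2), c(1, 1)), "non-negative")

  # survival starts at 1 and never increases; at-risk never increases
  set.seed(9)
  fit <- km_estimate(rexp(50, 0.1), rbinom(50, 1, 0.7))
  expect_true(all(diff(fit$surv) <= 1e-12))
  expect_true(all(fit$surv <= 1))
  expect_true(all(diff(fit$n_risk) <= 0))
})

test_that("log-rank comparison matches the hypergeometric-variance formula", {
  # 10-patient two-group example, evaluated independently
  times <- c(3, 5, 7, 9, 11, 4, 6, 8, 10, 12)
  events <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  grp <- rep(c("A", "B"), each = 5)
  df <- make_test_patients(10)
  df$os_months <- times
  df$event <- events
  ch <- mds_cohort(df)
  spec <- list(name = "arm", levels = c("A", "B"),
               fun = function(cohort, context) grp)
  gc_ <- km_by_factor(ch, spec)
  oracle <- logrank_oracle(times, events, grp)
  expect_equal(gc_$logrank_stat, oracle$stat, tolerance = 1e-9)
  expect_equal(gc_$p_value, oracle$p, tolerance = 1e-9)
  expect_equal(gc_$df, 1L)

  # two identical groups: statistic 0, p = 1
  df2 <- make_test_patients(10)
  df2$os_months <- rep(c(3, 6, 9, 12, 15), 2)
  df2$event <- rep(c(1, 0, 1, 1, 0), 2)
  spec2 <- list(name = "arm", levels = c("A", "B"),
                fun = function(cohort, context) rep(c("A", "B"), 5))
  gc2 <- km_by_factor(mds_cohort(df2), spec2)
  expect_equal(gc2$logrank_stat, 0, tolerance = 1e-12)
  expect_equal(gc2$p_value, 1)

  # permuting group labels leaves the p-value unchanged
  spec_flip <- list(name = "arm", levels = c("B", "A"),
                    fun = function(cohort, context) grp)
  expect_equal(km_by_factor(ch, spec_flip)$p_value, gc_$p_value)

  # adding a constant to all times leaves the log-rank p unchanged
  df3 <- df
  df3$os_months <- df3$os_months + 100
  expect_equal(km_by_factor(mds_cohort(df3), spec)$p_value, gc_$p_value)
})

test_that("poor-survival flag marks groups with median OS under 25 months", {
  arm <- planted_two_arm(200, 8, seed = 5, dropout = 0, baseline = 0.01,
                         horizon = 120)
  ch <- arm_cohort(arm, "TP53")
  gc_ <- suppressMessages(km_by_factor(ch, "gene:TP53"))
  gr <- gc_$groups
  expect_true(gr$poor_survival[gr$group == "mutated"])
  expect_false(gr$poor_survival[gr$group == "wild_type"])
})

test_that("Cox univariate recovers planted hazard ratios", {
  arm <- planted_two_arm(3000, 6.29, seed = 42)
  ch <- arm_cohort(arm, "TP53")
  res <- suppressMessages(cox_univariate(ch, "gene:TP53"))$table
  expect_gt(res$hr, 5.3)
  expect_lt(res$hr, 7.4)
  expect_true(res$converged)
  expect_lte(res$ci_lower, res$hr)
  expect_gte(res$ci_upper, res$hr)

  for (hr_true in c(0.5, 2)) {
    arm <- planted_two_arm(3000, hr_true, seed = 42)
    res <- suppressMessages(cox_univariate(arm_cohort(arm), "gene:TP53"))$table
    expect_lt(abs(log(res$hr) - log(hr_true)) / abs(log(hr_true)), 0.15)
  }
})

test_that("Cox CIs cover a null hazard ratio at the nominal rate", {
  hits <- 0
  for (r in 1:100) {
    arm <- planted_two_arm(2000, 1, seed = 5000 + r)
    fit <- survival::coxph(survival::Surv(arm$times, arm$events) ~ arm$x,
                           ties = "efron")
    ci <- exp(confint(fit))
    if (ci[1] <= 1 && ci[2] >= 1) hits <- hits + 1
  }
  expect_gte(hits, 93)
})

test_that("Cox estimates are invariant to time rescaling and flag bad inputs", {
  arm <- planted_two_arm(400, 2, seed = 77)
  ch <- arm_cohort(arm)
  res1 <- suppressMessages(cox_univariate(ch, "gene:TP53"))$table
  ch_days <- ch
  ch_days$patients$os_months <- ch$patients$os_months * 30.44
  res2 <- suppressMessages(cox_univariate(ch_days, "gene:TP53"))$table
  expect_equal(res1$hr, res2$hr, tolerance = 1e-9)

  # a constant covariate is inestimable
  expect_error(suppressMessages(cox_univariate(ch, "gene:ABSENT")),
               "inestimable")

  # complete separation flags non-convergence instead of failing silently
  sep <- make_test_patients(20)
  sep$os_months <- c(1:10, 101:110)
  sep$event <- rep(c(1, 0), each = 10)
  chs <- mds_cohort(sep)
  chs <- attach_mutations(chs, make_calls(sprintf("P%02d", 1:10), "TP53"))
  warns <- capture_warnings(res <- cox_univariate(chs, "gene:TP53"))
  expect_true(any(grepl("non-converged", warns)))
  expect_false(all(res$table$converged))
})

test_that("multivariate Cox handles orthogonal covariates and collinearity", {
  set.seed(88)
  n <- 5000
  x1 <- rbinom(n, 1, 0.4)
  x2 <- rbinom(n, 1, 0.3)
  lp <- log(2) * x1 + log(0.5) * x2
  tt <- rexp(n, rate = 0.02 * exp(lp))
  cens <- pmin(runif(n, 0, 200), 100)
  df <- make_test_patients(n)
  df$patient_id <- sprintf("Q%05d", 1:n)
  df$os_months <- pmin(tt, cens)
  df$event <- as.integer(tt <= cens)
  ch <- mds_cohort(df)
  ch <- attach_mutations(ch, rbind(
    make_calls(df$patient_id[x1 == 1], "TP53"),
    make_calls(df$patient_id[x2 == 1], "TET2")))

  multi <- suppressMessages(
    cox_multivariate(ch, c("gene:TP53", "gene:TET2")))$table
  expect_lt(abs(multi$hr[multi$variate == "gene:TP53"] - 2) / 2, 0.2)
  expect_lt(abs(multi$hr[multi$variate == "gene:TET2"] - 0.5) / 0.5, 0.2)

  # independent covariates: multivariate within 10% of univariate
  uni1 <- suppressMessages(cox_univariate(ch, "gene:TP53"))$table$hr
  expect_lt(abs(multi$hr[multi$variate == "gene:TP53"] - uni1) / uni1, 0.1)

  # the same covariate twice is exact collinearity, named in the error
  expect_error(suppressMessages(
    cox_multivariate(ch, c("gene:TP53", "gene:TP53"))),
    "collinear.*TP53")
  expect_error(cox_multivariate(ch, "gene:TP53"), ">= 2")
})

test_that("patients missing OS or event are excluded with a logged count", {
  df <- make_test_patients(6)
  df$os_months[2] <- NA
  ch <- mds_cohort(df)
  spec <- list(name = "half", levels = c("A", "B"),
               fun = function(cohort, context)
                 rep_len(c("A", "B"), nrow(cohort$patients)))
  expect_message(gc_ <- km_by_factor(ch, spec), "1 patient")
  expect_equal(sum(gc_$groups$n), 5)
})
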