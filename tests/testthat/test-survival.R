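test_that("Kaplan-Meier matches the hand-computed product limit", {
  df <- data.frame(t = c(1, 2, 3), e = c(1, 0, 1))
  td <- tidy(km_curve(df, t, e))
  expect_equal(td$estimate[td$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(td$estimate[td$time == 3], 0)
  # the subject censored at 2 left the risk set before time 3
  expect_equal(td$n_risk[td$time == 3], 1)
})

test_that("with no events the survival curve stays at 1", {
  df <- data.frame(t = c(2, 5, 9), e = c(0, 0, 0))
  td <- tidy(km_curve(df, t, e))
  expect_true(all(td$estimate == 1))
})

test_that("without censoring KM equals one minus the ECDF", {
  df <- withr::with_seed(12, data.frame(t = rexp(40, 0.1) + 0.01, e = 1))
  td <- tidy(km_curve(df, t, e))
  ecdf_t <- stats::ecdf(df$t)
  expect_equal(td$estimate, 1 - ecdf_t(td$time), tolerance = 1e-12)
  # and matches the step-by-step product-limit oracle
  oracle <- oracle_km(df$t, df$e)
  expect_equal(td$estimate[td$n_event > 0], oracle$surv, tolerance = 1e-12)
})

test_that("late censored-only subjects enlarge risk sets exactly as the product limit dictates", {
  # adding subjects censored after the last event raises every earlier
  # survival estimate through the bigger risk sets; the step-by-step
  # product-limit oracle pins the exact values
  df <- data.frame(t = c(1, 2, 3, 4), e = c(1, 1, 0, 1))
  extended <- rbind(df, data.frame(t = c(9, 11), e = c(0, 0)))
  a <- tidy(km_curve(df, t, e))
  b <- tidy(km_curve(extended, t, e))
  oracle_a <- oracle_km(df$t, df$e)
  oracle_b <- oracle_km(extended$t, extended$e)
  expect_equal(a$estimate[a$n_event > 0], oracle_a$surv, tolerance = 1e-12)
  expect_equal(b$estimate[b$n_event > 0], oracle_b$surv, tolerance = 1e-12)
  expect_true(all(oracle_b$surv > oracle_a$surv))
  # risk sets before the late entries grew by exactly the added subjects
  expect_equal(b$n_risk[b$time <= 4], a$n_risk + 2)
})

test_that("log-rank is exactly null for identical groups and matches hand tabulation", {
  df <- data.frame(
    t = rep(c(1, 3, 4, 7, 9), 2),
    e = rep(c(1, 0, 1, 1, 0), 2),
    g = rep(c("a", "b"), each = 5)
  )
  res <- logrank_test(df, t, e, g)
  expect_equal(res$chi_square, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)

  df2 <- data.frame(t = c(1, 2, 3, 4), e = 1, g = c("a", "a", "b", "b"))
  res2 <- logrank_test(df2, t, e, g)
  expect_equal(res2$chi_square, oracle_logrank(df2$t, df2$e, df2$g), tolerance = 1e-12)
})

test_that("log-rank refuses degenerate inputs", {
  expect_error(logrank_test(data.frame(t = 1:4, e = 0, g = rep(c("a", "b"), 2)),
                            t, e, g), "at least one event")
  expect_error(logrank_test(data.frame(t = 1:4, e = 1, g = "a"), t, e, g),
               "exactly two groups")
})

test_that("Cox estimates match a brute-force partial-likelihood grid search", {
  df <- make_survdata(20, seed = 91, beta = 0.8)
  fit <- cox_fit(df, time, event, "x")
  beta_grid <- oracle_cox_grid(df$time, df$event, df$x)
  expect_lt(abs(tidy(fit)$estimate - beta_grid), 1e-3)
  expect_equal(tidy(fit)$hazard_ratio, exp(tidy(fit)$estimate))
})

test_that("Cox coefficients are antisymmetric under binary label swap", {
  df <- make_survdata(60, seed = 15, beta = 0.7)
  swapped <- df; swapped$x <- 1 - df$x
  b1 <- tidy(cox_fit(df, time, event, "x"))$estimate
  b2 <- tidy(cox_fit(swapped, time, event, "x"))$estimate
  expect_equal(b1, -b2, tolerance = 1e-8)
})

test_that("log-rank chi-square equals the Cox score test on tie-free data", {
  df <- make_survdata(80, seed = 33, beta = 0.5)
  lr <- logrank_test(df, time, event, x)
  sc <- glance(cox_fit(df, time, event, "x"))$score_chi_square
  expect_equal(lr$chi_square, sc, tolerance = 1e-6)
})

test_that("constant covariates and zero-event groups are caught", {
  df <- make_survdata(30, seed = 44)
  df$z <- 1
  expect_error(cox_fit(df, time, event, "z"), "unidentifiable")

  sep <- data.frame(
    time = c(1, 2, 3, 4, 10, 11, 12, 13),
    event = c(1, 1, 1, 1, 0, 0, 0, 0),
    x = c(1, 1, 1, 1, 0, 0, 0, 0)
  )
  expect_warning(cox_fit(sep, time, event, "x"), "monotone")
})

test_that("Wald confidence intervals bracket the hazard ratio", {
  df <- make_survdata(150, seed = 2, beta = log(2))
  td <- tidy(cox_fit(df, time, event, "x"))
  expect_true(td$conf_low < td$hazard_ratio && td$hazard_ratio < td$conf_high)
  expect_equal(td$conf_low, exp(td$estimate - 1.96 * td$std_error), tolerance = 1e-12)
})

test_that("grouped KM tidy/glance report per-group curves and medians", {
  co <- generate_cohort(cohort_spec(n_subjects = 150, seed = 9))
  km <- km_curve(co, os_months, event, true_group)
  td <- tidy(km)
  expect_setequal(unique(td$group), c("low", "high"))
  expect_true(all(td$estimate >= 0 & td$estimate <= 1))
  # survival is non-increasing within each group
  for (g in c("low", "high")) {
    expect_true(all(diff(td$estimate[td$group == g]) <= 1e-12))
  }
  gl <- glance(km)
  expect_equal(sum(gl$n), 150)
})
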