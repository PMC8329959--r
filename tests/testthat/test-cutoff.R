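test_that("AUC handles perfect separation and uninformative markers", {
  expect_equal(roc_auc(c(1, 2, 10, 20), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(rep(3, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(roc_auc(c(1, 2, 10, 20), c(0, 0, 1, 1)), 0) # reversed marker
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("trapezoid AUC equals the pairwise and Mann-Whitney identities", {
  for (i in 1:100) {
    dat <- withr::with_seed(5000L + i, {
      n1 <- sample(3:20, 1); n0 <- sample(3:20, 1)
      list(
        v = c(sample(0:15, n1, replace = TRUE) + rnorm(n1, 0, 0.01 * (i %% 2)),
              sample(0:15, n0, replace = TRUE)),
        l = rep(c(1, 0), c(n1, n0))
      )
    })
    auc <- roc_auc(dat$v, dat$l, direction = "lower")
    expect_equal(auc, oracle_pairwise_auc(dat$v, dat$l, "lower"), tolerance = 1e-12)
    # U of "survivor value exceeds death value" over n1*n0 pairs
    u <- texsurv:::mw_core(dat$v[dat$l == 0], dat$v[dat$l == 1])$u
    expect_equal(auc, u / (sum(dat$l == 1) * sum(dat$l == 0)), tolerance = 1e-12)
  }
})

test_that("optimal cutoff equals the exhaustive Youden scan", {
  for (i in 1:100) {
    dat <- withr::with_seed(6000L + i, {
      n <- sample(10:60, 1)
      list(v = round(rnorm(n, 50, 20)), l = rbinom(n, 1, 0.4))
    })
    if (length(unique(dat$l)) < 2) next
    res <- optimal_cutoff(dat$v, dat$l)
    oracle <- oracle_cutoff_scan(dat$v, dat$l)
    expect_equal(res$cutoff, oracle$cutoff)
    expect_equal(res$youden_j, oracle$j, tolerance = 1e-12)
  }
})

test_that("perfect separation attains J = 1 at the tie-broken larger cutoff", {
  res <- optimal_cutoff(c(1, 2, 10, 20), c(1, 1, 0, 0))
  expect_equal(res$youden_j, 1)
  expect_equal(res$cutoff, 10) # the only observed value attaining J = 1
  # two observed values attain the maximal J: the larger must win
  res2 <- optimal_cutoff(c(1, 5, 5, 10), c(1, 1, 0, 0))
  expect_equal(res2$youden_j, 0.5)
  expect_equal(res2$cutoff, 10) # J = 0.5 at both 5 and 10; tie-break upward
})

test_that("null-label cutoffs overfit only moderately at n = 98", {
  js <- vapply(1:500, function(i) {
    dat <- withr::with_seed(7000L + i, {
      list(v = rnorm(98, 60, 20), l = rbinom(98, 1, 0.42))
    })
    if (length(unique(dat$l)) < 2) return(NA_real_)
    optimal_cutoff(dat$v, dat$l)$youden_j
  }, numeric(1))
  expect_lt(mean(js, na.rm = TRUE), 0.35)
})

test_that("dichotomization uses a strict < rule and conserves subjects", {
  df <- data.frame(v = c(66.78, 66.79, 66.80), event = c(1, 0, 0))
  out <- dichotomize(df, v, 66.79)
  expect_equal(as.character(out$group), c("low", "high", "high"))
  expect_equal(levels(out$group), c("high", "low")) # high is the reference

  df2 <- withr::with_seed(8, data.frame(v = c(rnorm(20, 50, 10), NA, NA)))
  expect_warning(dichotomize(df2, v, 50), "missing")
  out2 <- suppressWarnings(dichotomize(df2, v, 50))
  counts <- attr(out2, "group_counts")
  expect_equal(sum(counts), 20L)
  expect_equal(nrow(out2), 20L)
})

test_that("an empty side of the cutoff is flagged as degenerate", {
  df <- data.frame(v = c(1, 2, 3))
  expect_warning(dichotomize(df, v, 10), "empty group")
  out <- suppressWarnings(dichotomize(df, v, 10))
  expect_true(attr(out, "degenerate"))
  expect_equal(unname(attr(out, "group_counts")["high"]), 0L)
})

test_that("feature_cutoffs maps over features and excludes missing values per feature", {
  co <- generate_cohort(cohort_spec(n_subjects = 120, seed = 17))
  df <- data.frame(event = co$event, mpp = co$feature, entropy = co$feature / 10)
  df$mpp[1:3] <- NA
  out <- feature_cutoffs(df, features = c("mpp", "entropy"))
  expect_equal(out$feature, c("mpp", "entropy"))
  expect_equal(out$n_events[1] + out$n_nonevents[1], sum(!is.na(df$mpp)))
  direct <- optimal_cutoff(df$entropy, df$event, feature = "entropy")
  expect_equal(out$cutoff[2], direct$cutoff)
})
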