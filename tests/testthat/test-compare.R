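test_that("Levene's statistic is zero for identical groups and matches a hand ANOVA", {
  df <- data.frame(v = c(1, 5, 9, 1, 5, 9), g = rep(c("a", "b"), each = 3))
  res <- levene_test(df, v, g)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # hand ANOVA on |x - group mean| for {1,2,3} vs {10,20,30}
  df2 <- data.frame(v = c(1, 2, 3, 10, 20, 30), g = rep(c("a", "b"), each = 3))
  z <- c(abs(c(1, 2, 3) - 2), abs(c(10, 20, 30) - 20))
  grp <- rep(c(0, 1), each = 3)
  ssb <- 3 * (mean(z[grp == 0]) - mean(z))^2 + 3 * (mean(z[grp == 1]) - mean(z))^2
  ssw <- sum((z[grp == 0] - mean(z[grp == 0]))^2) + sum((z[grp == 1] - mean(z[grp == 1]))^2)
  f_oracle <- (ssb / 1) / (ssw / 4)
  expect_equal(levene_test(df2, v, g)$statistic, f_oracle, tolerance = 1e-12)
})

test_that("Levene's test holds its nominal size under the null", {
  rejections <- vapply(1:1000, function(i) {
    df <- withr::with_seed(3000L + i, data.frame(
      v = rnorm(30), g = rep(c("a", "b", "c"), each = 10)
    ))
    levene_test(df, v, g)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("Levene rejects groups that are too small", {
  df <- data.frame(v = c(1, 2, 3), g = c("a", "a", "b"))
  expect_error(levene_test(df, v, g), "at least two observations")
})

test_that("Mann-Whitney U and exact p match enumeration on small samples", {
  sep <- data.frame(v = c(1, 2, 3, 4), g = c("a", "a", "b", "b"))
  res <- mann_whitney(sep, v, g)
  expect_equal(res$u_statistic, 0) # complete separation: no a > b pair
  inter <- data.frame(v = c(1, 3, 2, 4), g = c("a", "a", "b", "b"))
  res2 <- mann_whitney(inter, v, g)
  expect_equal(res2$p_value, 2 / 3, tolerance = 1e-12)
  expect_equal(res2$method, "exact")
})

test_that("swapping groups maps U to n1*n2 - U and keeps the p-value", {
  df <- withr::with_seed(4, data.frame(
    v = round(rnorm(10, 0, 3)), g = rep(c("a", "b"), each = 5)
  ))
  swapped <- df
  swapped$g <- ifelse(df$g == "a", "zb", "aa") # reverses factor order
  r1 <- mann_whitney(df, v, g)
  r2 <- mann_whitney(swapped, v, g)
  expect_equal(r2$u_statistic, r1$n_a * r1$n_b - r1$u_statistic)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
})

test_that("large-sample p agrees with the classic normal approximation", {
  df <- withr::with_seed(6, data.frame(
    v = c(rnorm(20, 0), rnorm(25, 0.5)), g = rep(c("a", "b"), c(20, 25))
  ))
  res <- mann_whitney(df, v, g)
  ref <- stats::wilcox.test(v ~ g, data = df, exact = FALSE, correct = FALSE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(res$u_statistic, unname(ref$statistic))
  expect_equal(res$method, "normal approximation")
})

test_that("fully tied data is flagged degenerate with p = 1", {
  df <- data.frame(v = rep(5, 8), g = rep(c("a", "b"), 4))
  res <- mann_whitney(df, v, g)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("Spearman collinearity reproduces the rank-then-Pearson oracle", {
  df <- data.frame(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3), c = c(-1, -2, -3, -4))
  out <- spearman_matrix(df, features = c("a", "b", "c"))
  ab <- out[out$feature_a == "a" & out$feature_b == "b", ]
  expect_equal(ab$rho, stats::cor(rank(df$a), rank(df$b)), tolerance = 1e-12)
  expect_equal(ab$rho, 0.6) # 1 - 6*4/(4*15) by the rank-difference formula
  ac <- out[out$feature_a == "a" & out$feature_b == "c", ]
  expect_equal(ac$rho, -1)
})

test_that("constant features yield a flagged NA correlation", {
  df <- data.frame(a = 1:6, b = rep(2, 6))
  out <- spearman_matrix(df, features = c("a", "b"))
  expect_true(out$degenerate)
  expect_true(is.na(out$rho))
})

test_that("survivor vs non-survivor comparison table carries per-scale MW results", {
  co <- generate_cohort(cohort_spec(n_subjects = 80, seed = 21))
  feats <- data.frame(subject_id = co$subject_id, ssf = 0, mpp = co$feature)
  joined <- merge(feats, co[c("subject_id", "event")])
  tab <- compare_by_survival(joined, features = "mpp")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_survivors + tab$n_nonsurvivors, 80L)
  direct <- mann_whitney(joined, mpp, event)
  expect_equal(tab$p_value, direct$p_value)
})
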