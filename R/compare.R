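#' Levene's test for equality of variances
#'
#' Classic (mean-centred) Levene test: a one-way ANOVA on the absolute
#' deviations of each observation from its group mean, with an
#' F-distribution p-value. Used as a variance-homogeneity check before
#' group comparisons.
#'
#' @param data A data frame.
#' @param value Column of measurements (tidy-eval).
#' @param group Column of group labels (tidy-eval); two or more groups,
#'   each with at least two observations.
#'
#' @return A one-row tibble: `statistic`, `df`, `df_resid`, `p_value`.
#' @export
#' @examples
#' df <- data.frame(v = c(1, 2, 3, 10, 20, 30), g = rep(c("a", "b"), each = 3))
#' levene_test(df, v, g)
levene_test <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("Levene's test needs at least two groups.")
  if (any(table(g) < 2)) abort("every group needs at least two observations.")
  res <- car::leveneTest(v, g, center = mean)
  tibble(
    statistic = res[["F value"]][1],
    df = res[["Df"]][1],
    df_resid = res[["Df"]][2],
    p_value = res[["Pr(>F)"]][1]
  )
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of a measurement between two groups, with midranks
#' for ties. The U statistic counts pairs where the first group's value
#' exceeds the second's (ties count 1/2). For small samples
#' (\eqn{n_1 + n_2 \le 12}) the two-sided p-value is exact, by full
#' enumeration of all group labelings of the pooled sample; otherwise the
#' normal approximation with the tie-corrected variance is used (no
#' continuity correction). If every pooled value is identical the result is
#' flagged degenerate with p = 1.
#'
#' @param data A data frame.
#' @param value Column of measurements (tidy-eval).
#' @param group Column with exactly two group labels (tidy-eval).
#'
#' @return A one-row tibble: `group_a`, `group_b`, `n_a`, `n_b`,
#'   `u_statistic` (pairs where a > b), `p_value`, `median_a`, `median_b`,
#'   `method`, `degenerate`.
#' @export
#' @examples
#' df <- data.frame(v = c(1, 3, 2, 4), g = c("a", "a", "b", "b"))
#' mann_whitney(df, v, g)  # exact p = 2/3
mann_whitney <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) != 2) abort("Mann-Whitney requires exactly two groups.")
  a <- v[g == levels(g)[1]]
  b <- v[g == levels(g)[2]]
  res <- mw_core(a, b)
  tibble(
    group_a = levels(g)[1], group_b = levels(g)[2],
    n_a = length(a), n_b = length(b),
    u_statistic = res$u, p_value = res$p,
    median_a = median(a), median_b = median(b),
    method = res$method, degenerate = res$degenerate
  )
}

# U statistic (pairs a > b, ties 1/2) and two-sided p for two samples
mw_core <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (!n1 || !n2) abort("both groups must be non-empty.")
  pooled <- c(a, b)
  r <- rank(pooled)                       # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1L) {
    return(list(u = u, p = 1, method = "degenerate", degenerate = TRUE))
  }
  mu <- n1 * n2 / 2
  if (n1 + n2 <= 12L) {
    # exact: U under every labeling of the pooled (mid)ranks
    combos <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    n <- n1 + n2
    ties <- table(pooled)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(u = u, p = min(p, 1), method = method, degenerate = FALSE)
}

#' Compare texture features between survivors and non-survivors
#'
#' Per feature and SSF scale, summarizes each outcome group (mean +/- SD)
#' and tests the distributional difference with [mann_whitney()].
#'
#' @param data Data frame of per-subject feature values joined to outcome;
#'   must contain `event` (1 = death) and, if per-scale, `ssf`.
#' @param features Character vector of feature columns to compare.
#'
#' @return A tibble with one row per (ssf, feature): group sizes, group
#'   means and SDs, U and p-value.
#' @export
compare_by_survival <- function(data,
                                features = c("mean", "sd", "mpp", "entropy",
                                             "skewness", "kurtosis")) {
  check_cols(data, c("event", intersect(features, names(data))))
  features <- intersect(features, names(data))
  if (!"ssf" %in% names(data)) data$ssf <- NA_real_
  scales <- unique(data$ssf)
  scales <- scales[order(scales, na.last = TRUE)]
  purrr::map_dfr(scales, function(s) {
    slice <- data[if (is.na(s)) is.na(data$ssf) else !is.na(data$ssf) & data$ssf == s, ]
    purrr::map_dfr(features, function(f) {
      vals <- slice[[f]]
      keep <- is.finite(vals)
      d <- vals[keep & slice$event == 1]
      sv <- vals[keep & slice$event == 0]
      res <- mw_core(sv, d)
      tibble(
        ssf = s, feature = f,
        n_survivors = length(sv), n_nonsurvivors = length(d),
        mean_survivors = mean(sv), sd_survivors = stats::sd(sv),
        mean_nonsurvivors = mean(d), sd_nonsurvivors = stats::sd(d),
        u_statistic = res$u, p_value = res$p
      )
    })
  })
}

#' Pairwise Spearman collinearity of texture features
#'
#' Spearman rank correlation (midrank ties) between every pair of feature
#' columns, with two-sided p-values from the t approximation. Constant
#' features yield an `NA` correlation flagged in the output rather than an
#' error.
#'
#' @param data Data frame of per-subject feature values (one scale).
#' @param features Character vector of feature columns.
#'
#' @return A tibble with one row per unordered pair: `feature_a`,
#'   `feature_b`, `rho`, `p_value`, `n`, `degenerate`.
#' @export
spearman_matrix <- function(data,
                            features = c("mean", "sd", "mpp", "entropy",
                                         "skewness", "kurtosis")) {
  features <- intersect(features, names(data))
  if (length(features) < 2) abort("need at least two feature columns.")
  pairs <- utils::combn(features, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    x <- data[[pr[1]]]; y <- data[[pr[2]]]
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3) abort("Spearman correlation needs at least 3 complete subjects.")
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
      return(tibble(feature_a = pr[1], feature_b = pr[2], rho = NA_real_,
                    p_value = NA_real_, n = length(x), degenerate = TRUE))
    }
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    tibble(feature_a = pr[1], feature_b = pr[2],
           rho = unname(ct$estimate), p_value = ct$p.value,
           n = length(x), degenerate = FALSE)
  })
}
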