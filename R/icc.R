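#' Intraclass correlation coefficient (single measures)
#'
#' Two-way random-effects ICC from the standard ANOVA mean squares of a
#' subjects-by-raters matrix: with `n` subjects, `k` raters, between-subject
#' mean square MSR, between-rater mean square MSC and residual mean square
#' MSE,
#' \deqn{\mathrm{ICC}(\mathrm{agreement}) =
#'   \frac{MSR - MSE}{MSR + (k-1)\,MSE + \frac{k}{n}(MSC - MSE)}}
#' \deqn{\mathrm{ICC}(\mathrm{consistency}) =
#'   \frac{MSR - MSE}{MSR + (k-1)\,MSE}}
#' Absolute agreement (the default) penalizes systematic rater offsets;
#' consistency does not.
#'
#' @param ratings Numeric matrix or data frame, subjects in rows, repeated
#'   ratings/raters in columns; at least 5 subjects, 2 ratings, no missing
#'   cells.
#' @param type `"agreement"` (two-way random, absolute agreement, single
#'   measures) or `"consistency"`.
#'
#' @return The ICC, a single number `<= 1`; `NA` with a warning when the
#'   between-subject variance is zero (the coefficient is undefined).
#' @export
#' @examples
#' m <- cbind(r1 = c(1, 2, 3, 4, 5, 6), r2 = c(1.1, 2, 2.9, 4.2, 5, 6.1))
#' icc(m)
icc <- function(ratings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  m <- as.matrix(ratings)
  if (!is.numeric(m)) abort("`ratings` must be numeric.")
  if (anyNA(m)) abort("`ratings` must have no missing cells.")
  n <- nrow(m); k <- ncol(m)
  if (n < 5) abort("ICC needs at least 5 subjects.")
  if (k < 2) abort("ICC needs at least 2 ratings per subject.")

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  if (msr < .Machine$double.eps * max(1, grand^2)) {
    warn("zero between-subject variance; ICC is undefined (NA).")
    return(NA_real_)
  }
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Qualitative agreement band for an ICC value
#'
#' Maps an ICC to the conventional agreement labels: 1 is perfect
#' agreement; 0.81-0.99 almost perfect; 0.61-0.80 substantial; 0.41-0.60
#' moderate; 0.21-0.40 fair; and at or below 0.20 slight. The printed bands
#' do not tile the whole interval, so values falling in a gap (e.g.
#' between 0.99 and 1) are assigned to the nearest lower band. Values
#' above 1 are an error.
#'
#' @param value Numeric vector of ICC values, each `<= 1`.
#' @return Character vector of band labels.
#' @export
#' @examples
#' categorize_agreement(c(1, 0.77, 0.2))
categorize_agreement <- function(value) {
  if (any(is.na(value))) abort("ICC value is NA; no agreement band applies.")
  if (any(value > 1 + 1e-12)) abort("ICC cannot exceed 1.")
  dplyr::case_when(
    value >= 1 - 1e-12 ~ "perfect agreement",
    value > 0.80 ~ "almost perfect agreement",
    value > 0.60 ~ "substantial agreement",
    value > 0.40 ~ "moderate agreement",
    value > 0.20 ~ "fair agreement",
    TRUE ~ "slight agreement"
  )
}

#' Per-feature ICC table between two readings
#'
#' Joins two per-subject feature tables (reader A vs reader B, or repeat
#' measurements by one reader) on `subject_id` (and `ssf` when present)
#' and computes the ICC and agreement band for each feature at each scale.
#'
#' @param reading_a,reading_b Data frames with `subject_id`, optionally
#'   `ssf`, and feature columns.
#' @param features Character vector of feature columns.
#' @param type ICC form, see [icc()].
#'
#' @return A tibble with one row per (ssf, feature): `icc`, `category`,
#'   `n_subjects`, `n_ratings`.
#' @export
icc_table <- function(reading_a, reading_b,
                      features = c("mean", "sd", "mpp", "entropy",
                                   "skewness", "kurtosis"),
                      type = "agreement") {
  check_cols(reading_a, "subject_id"); check_cols(reading_b, "subject_id")
  keys <- intersect(c("subject_id", "ssf"), intersect(names(reading_a), names(reading_b)))
  features <- intersect(features, intersect(names(reading_a), names(reading_b)))
  joined <- dplyr::inner_join(reading_a, reading_b, by = keys,
                              suffix = c("_a", "_b"))
  if (length(unique(joined$subject_id)) < 5) {
    abort("fewer than 5 shared subjects between the two readings.")
  }
  if (!"ssf" %in% keys) joined$ssf <- NA_real_
  purrr::map_dfr(split(joined, factor(joined$ssf, exclude = NULL)), function(slice) {
    purrr::map_dfr(features, function(f) {
      m <- cbind(slice[[paste0(f, "_a")]], slice[[paste0(f, "_b")]])
      ok <- complete.cases(m)
      val <- icc(m[ok, , drop = FALSE], type = type)
      tibble(
        ssf = slice$ssf[1], feature = f, icc = val,
        category = if (is.na(val)) NA_character_ else categorize_agreement(val),
        n_subjects = sum(ok), n_ratings = 2L
      )
    })
  })
}
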