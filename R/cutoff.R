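#' Area under the ROC curve for a prognostic rule
#'
#' Empirical AUC of a continuous marker against a binary outcome, computed
#' by the trapezoidal rule over the full threshold scan of the ROC curve.
#' The default direction follows the prognostic convention for
#' post-contrast tumor attenuation: lower values predict death
#' (`direction = "lower"`). Ties between the classes receive half credit
#' (they appear as diagonal ROC segments, which the trapezoid halves).
#'
#' @param values Numeric marker values.
#' @param labels Binary outcome, 1 = death (positive class), 0 = survivor.
#' @param direction `"lower"` if smaller values predict death, `"higher"`
#'   otherwise.
#'
#' @return The AUC, a single number in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(1, 2, 10, 20), c(1, 1, 0, 0))  # perfect separation: 1
roc_auc <- function(values, labels, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  pts <- roc_points(values, labels, direction)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

# ROC curve points over all distinct thresholds (score = oriented value)
roc_points <- function(values, labels, direction) {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (!length(values)) abort("no complete observations for ROC analysis.")
  if (length(unique(labels)) < 2) {
    abort("ROC analysis needs both outcome classes present.")
  }
  score <- if (direction == "lower") -values else values
  ord <- order(score, decreasing = TRUE)
  score <- score[ord]; lab <- labels[ord]
  n_pos <- sum(lab == 1); n_neg <- sum(lab == 0)
  # cumulative counts at each distinct score (ties grouped)
  last_of_run <- c(score[-1] != score[-length(score)], TRUE)
  tp <- cumsum(lab == 1)[last_of_run]
  fp <- cumsum(lab == 0)[last_of_run]
  tibble(tpr = c(0, tp / n_pos), fpr = c(0, fp / n_neg))
}

#' ROC-optimal cutoff for dichotomizing a texture feature
#'
#' Scans every observed marker value as a candidate cutoff for the
#' decision rule "value < cutoff predicts death" (direction `"lower"`; the
#' rule is reversed for `"higher"`), and returns the cutoff maximizing
#' Youden's J = sensitivity + specificity - 1. Ties on J are broken toward
#' the larger cutoff, i.e. the more inclusive low-value group. The AUC of
#' the underlying ROC curve is reported alongside.
#'
#' @inheritParams roc_auc
#' @param feature Optional feature name carried into the result.
#'
#' @return A one-row tibble: `feature`, `cutoff` (an observed value),
#'   `auc`, `youden_j`, `sensitivity`, `specificity`, `direction`,
#'   `n_events`, `n_nonevents`.
#' @export
#' @examples
#' optimal_cutoff(c(1, 2, 10, 20), c(1, 1, 0, 0))  # cutoff 10, J = 1
optimal_cutoff <- function(values, labels, direction = c("lower", "higher"),
                           feature = NA_character_) {
  direction <- match.arg(direction)
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2) {
    abort("cutoff selection needs both outcome classes present.")
  }
  candidates <- sort(unique(values))
  stats_at <- function(c0) {
    pred_death <- if (direction == "lower") values < c0 else values > c0
    sens <- mean(pred_death[labels == 1])
    spec <- mean(!pred_death[labels == 0])
    c(sens = sens, spec = spec, j = sens + spec - 1)
  }
  grid <- vapply(candidates, stats_at, numeric(3))
  best_j <- max(grid["j", ])
  # ties toward the larger cutoff (more inclusive low group)
  best <- max(which(grid["j", ] >= best_j - 1e-12))
  tibble(
    feature = feature,
    cutoff = candidates[best],
    auc = roc_auc(values, labels, direction),
    youden_j = unname(grid["j", best]),
    sensitivity = unname(grid["sens", best]),
    specificity = unname(grid["spec", best]),
    direction = direction,
    n_events = sum(labels == 1),
    n_nonevents = sum(labels == 0)
  )
}

#' Compute optimal cutoffs for several features at once
#'
#' Data-frame-first wrapper around [optimal_cutoff()]: one row of cutoff
#' results per feature column, using the `event` column as the outcome.
#' Subjects with a missing value of a given feature are excluded from that
#' feature's analysis.
#'
#' @param data Data frame with `event` plus the feature columns.
#' @param features Character vector of feature columns.
#' @param direction Direction passed to [optimal_cutoff()].
#'
#' @return A tibble with one row per feature.
#' @export
feature_cutoffs <- function(data,
                            features = c("mean", "sd", "mpp", "entropy"),
                            direction = "lower") {
  check_cols(data, "event")
  features <- intersect(features, names(data))
  purrr::map_dfr(features, function(f) {
    optimal_cutoff(data[[f]], data$event, direction = direction, feature = f)
  })
}

#' Dichotomize subjects at a feature cutoff
#'
#' Adds a `group` factor to the data: `"low"` when the feature value is
#' strictly below the cutoff, `"high"` otherwise (so the cutoff value
#' itself falls in the high group, matching the usual ">= cutoff" reference
#' row of survival tables). The factor's reference level is `"high"`, so a
#' Cox coefficient on `group` measures the low-group hazard. Subjects with
#' a missing feature value are dropped with a warning.
#'
#' @param data Data frame.
#' @param value Feature column (tidy-eval).
#' @param cutoff Finite cutoff on the feature scale.
#'
#' @return `data` (minus missing-feature rows) with a `group` column.
#'   Group counts are in the `"group_counts"` attribute; if either group is
#'   empty a warning is raised and the `"degenerate"` attribute is `TRUE`.
#' @export
dichotomize <- function(data, value, cutoff) {
  if (!is.finite(cutoff)) abort("`cutoff` must be finite.")
  v <- dplyr::pull(data, {{ value }})
  missing <- !is.finite(v)
  if (any(missing)) {
    warn(sprintf("excluding %d subject(s) with missing feature values.", sum(missing)))
    data <- data[!missing, , drop = FALSE]
    v <- v[!missing]
  }
  data$group <- factor(ifelse(v < cutoff, "low", "high"), levels = c("high", "low"))
  counts <- table(data$group)
  degenerate <- any(counts == 0)
  if (degenerate) {
    warn("dichotomization produced an empty group; downstream KM/Cox will refuse it.")
  }
  attr(data, "group_counts") <- counts
  attr(data, "degenerate") <- degenerate
  data
}
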