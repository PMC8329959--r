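#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of overall survival, optionally stratified by a
#' grouping column. Subjects censored at an event time are kept in the
#' risk set for that event (the standard convention).
#'
#' @param data Data frame.
#' @param time Follow-up time column, months (tidy-eval); must be positive.
#' @param event Event indicator column (1 = death, 0 = censored).
#' @param group Optional grouping column (tidy-eval).
#'
#' @return An object of class `texsurv_km` wrapping the
#'   [survival::survfit()] fit; use [tidy()] for the curve table and
#'   [ggplot2::autoplot()] to draw it.
#' @export
#' @examples
#' df <- data.frame(t = c(1, 2, 3), e = c(1, 0, 1))
#' tidy(km_curve(df, t, e))
km_curve <- function(data, time, event, group = NULL) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  if (any(!is.finite(t)) || any(t <= 0)) abort("times must be positive and finite.")
  if (!all(e %in% c(0, 1))) abort("`event` must be 0 (censored) or 1 (death).")
  g <- rlang::enquo(group)
  df <- data.frame(.time = t, .event = e)
  if (!rlang::quo_is_null(g)) {
    df$.group <- factor(dplyr::pull(data, !!g))
    fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df)
  } else {
    fit <- survival::survfit(survival::Surv(.time, .event) ~ 1, data = df)
  }
  structure(list(fit = fit, grouped = !rlang::quo_is_null(g)),
            class = "texsurv_km")
}

#' Curve table of a Kaplan-Meier fit
#'
#' One row per distinct time, with at-risk counts, events, censorings, the
#' survival estimate and its Greenwood confidence band (and `group` when
#' stratified).
#' @param x A `texsurv_km` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
#' @export tidy.texsurv_km
tidy.texsurv_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  out <- tibble(
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    n_censor = s$n.censor,
    estimate = s$surv,
    std_error = s$std.err,
    conf_low = s$lower,
    conf_high = s$upper
  )
  if (x$grouped) {
    out$group <- sub("^\\.group=", "", as.character(s$strata))
    out <- dplyr::relocate(out, "group")
  }
  out
}

#' Per-group summary of a Kaplan-Meier fit: subjects, events, median survival
#' @param x A `texsurv_km` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::glance
#' @export glance.texsurv_km
glance.texsurv_km <- function(x, ...) {
  tab <- summary(x$fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, 1, dimnames = list("all", names(tab)))
  tibble(
    group = sub("^\\.group=", "", rownames(tab)),
    n = tab[, "records"],
    n_events = tab[, "events"],
    median_survival = tab[, "median"]
  )
}

#' Step-function plot of Kaplan-Meier curve(s) with censor ticks
#' @param object A `texsurv_km` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export autoplot.texsurv_km
autoplot.texsurv_km <- function(object, ...) {
  df <- tidy(object)
  if (!object$grouped) df$group <- "all"
  start <- dplyr::distinct(df, .data$group)
  start <- dplyr::mutate(start, time = 0, estimate = 1)
  df2 <- dplyr::bind_rows(start, df[c("group", "time", "estimate", "n_censor")])
  df2 <- dplyr::arrange(df2, .data$group, .data$time)
  p <- ggplot2::ggplot(df2, ggplot2::aes(.data$time, .data$estimate,
                                         colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = dplyr::filter(df2, !is.na(.data$n_censor) & .data$n_censor > 0),
      shape = 3
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Overall survival", colour = NULL)
  if (!object$grouped) p <- p + ggplot2::guides(colour = "none")
  p
}

#' Log-rank test between two survival curves
#'
#' Standard (unweighted) log-rank test: observed minus expected events
#' summed over distinct event times with the hypergeometric variance,
#' referred to a chi-square distribution on 1 degree of freedom.
#'
#' @inheritParams km_curve
#' @param group Grouping column with exactly two levels (tidy-eval).
#'
#' @return A one-row tibble: `chi_square`, `df`, `p_value`, `n_a`, `n_b`,
#'   `events_a`, `events_b`.
#' @export
logrank_test <- function(data, time, event, group) {
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  if (nlevels(g) != 2) abort("log-rank comparison requires exactly two groups.")
  if (any(table(g) == 0)) abort("both groups must be non-empty.")
  if (sum(e) < 1) abort("log-rank test needs at least one event.")
  if (any(!is.finite(t)) || any(t <= 0)) abort("times must be positive and finite.")
  df <- data.frame(.time = t, .event = e, .group = g)
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = df)
  tibble(
    chi_square = sd$chisq,
    df = 1L,
    p_value = pchisq(sd$chisq, 1, lower.tail = FALSE),
    n_a = sd$n[1], n_b = sd$n[2],
    events_a = sd$obs[1], events_b = sd$obs[2]
  )
}

#' Cox proportional-hazards model
#'
#' Fits a Cox model by partial-likelihood maximization (Newton-Raphson,
#' Efron correction for tied event times) and reports, per coefficient,
#' the hazard ratio with Wald 95% confidence interval and p-value. Designed
#' for the univariate analyses of single clinical variables or
#' dichotomized texture features, and for bivariate feature + M-stage
#' models; any covariate list is accepted.
#'
#' A covariate that is constant across subjects is rejected as
#' unidentifiable. Monotone likelihood (e.g. a group with no events) is
#' detected from the fit and flagged with a warning, never returned
#' silently.
#'
#' @inheritParams km_curve
#' @param covariates Character vector of covariate column names.
#' @param ties Tie correction for the partial likelihood: `"efron"`
#'   (default; exact when there are no ties) or `"breslow"`.
#'
#' @return An object of class `texsurv_cox`; see [tidy.texsurv_cox()] and
#'   [glance.texsurv_cox()].
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 120, seed = 3))
#' fit <- cox_fit(cohort, os_months, event, "true_group")
#' tidy(fit)
cox_fit <- function(data, time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  t <- dplyr::pull(data, {{ time }})
  e <- dplyr::pull(data, {{ event }})
  if (any(!is.finite(t)) || any(t <= 0)) abort("times must be positive and finite.")
  if (sum(e) < 1) abort("Cox regression needs at least one event.")
  check_cols(data, covariates)
  model_df <- data.frame(.time = t, .event = e,
                         data[covariates], check.names = FALSE)
  model_df <- model_df[complete.cases(model_df), , drop = FALSE]
  for (cv in covariates) {
    x <- model_df[[cv]]
    if (length(unique(x[!is.na(x)])) < 2) {
      abort(sprintf("covariate `%s` is constant; the model is unidentifiable.", cv))
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  warned <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = model_df, ties = ties,
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  monotone <- any(grepl("infinite|converge|beta may be infinite", warned,
                        ignore.case = TRUE)) || any(abs(stats::coef(fit)) > 15)
  converged <- fit$iter < 100 && !any(grepl("Ran out of iterations", warned))
  if (monotone) {
    warn(paste("possible monotone partial likelihood (a group may have no",
               "events); hazard-ratio estimates are unreliable."))
  }
  structure(
    list(fit = fit, covariates = covariates, converged = converged,
         monotone = monotone, n = nrow(model_df), n_events = sum(model_df$.event)),
    class = "texsurv_cox"
  )
}

#' Tidy a Cox fit
#'
#' @param x A `texsurv_cox` object.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate` (log
#'   hazard), `std_error`, `hazard_ratio`, `conf_low`, `conf_high` (Wald
#'   95%), `p_value`.
#' @exportS3Method generics::tidy
#' @export tidy.texsurv_cox
tidy.texsurv_cox <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(
    term = rownames(co),
    estimate = co[, "coef"],
    std_error = co[, "se(coef)"],
    hazard_ratio = exp(co[, "coef"]),
    conf_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    conf_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"]
  )
}

#' One-row summary of a Cox fit
#'
#' @param x A `texsurv_cox` object.
#' @param ... Unused.
#' @return A tibble: `n`, `n_events`, `log_likelihood` (maximized partial),
#'   `score_chi_square`, `converged`, `monotone`.
#' @exportS3Method generics::glance
#' @export glance.texsurv_cox
glance.texsurv_cox <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = x$n,
    n_events = x$n_events,
    log_likelihood = x$fit$loglik[2],
    score_chi_square = unname(s$sctest["test"]),
    converged = x$converged,
    monotone = x$monotone
  )
}

#' @export
print.texsurv_cox <- function(x, ...) {
  cat(sprintf("<texsurv_cox> n=%d, events=%d, converged=%s%s\n",
              x$n, x$n_events, x$converged,
              if (x$monotone) " [monotone likelihood]" else ""))
  print(tidy(x))
  invisible(x)
}
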