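#' Build a pipeline run configuration
#'
#' Merges package defaults, an optional YAML config file, and direct
#' overrides (in increasing priority) into the configuration consumed by
#' the `run_*` orchestration functions. All randomness used by a run flows
#' from `seed`.
#'
#' Fields: `seed`; `out_dir` (`NULL` keeps results in memory);
#' `scales` (SSF scales, mm); `bin_width` (entropy bin, HU); `cutoff_ssf`
#' (scale whose features are dichotomized); `direction` (ROC direction);
#' `alpha`; `p_adjust` (`"none"` or `"holm"`); `icc_type`; `cox_ties`;
#' `features` (feature columns entering the cutoff/Cox chain);
#' `n_subjects`; `phantom` (argument list for [phantom_spec()]); `cohort`
#' (argument list for [cohort_spec()]); `core_fraction_low` /
#' `core_fraction_high` (necrotic-core extent by prognostic group in
#' simulated phantoms); `reader_jitter` (relative ROI-radius perturbation
#' emulating a second reader); `paths` (named list: `manifest`,
#' `clinical`, `features`, `reading_a`, `reading_b`).
#'
#' @param path Optional YAML file.
#' @param ... Named overrides of individual fields.
#' @return A list of class `texsurv_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    scales = c(0, 2, 3, 4, 5, 6),
    bin_width = 1,
    cutoff_ssf = 0,
    direction = "lower",
    alpha = 0.05,
    p_adjust = "none",
    icc_type = "agreement",
    cox_ties = "efron",
    features = c("mean", "sd", "mpp", "entropy"),
    n_subjects = 98L,
    phantom = list(),
    cohort = list(),
    core_fraction_low = 0.55,
    core_fraction_high = 0.15,
    reader_jitter = 0.05,
    paths = list()
  )
  config <- defaults
  if (!is.null(path)) {
    config <- utils::modifyList(config, yaml::read_yaml(path))
  }
  config <- utils::modifyList(config, list(...))
  if (config$alpha <= 0 || config$alpha >= 1) abort("`alpha` must be in (0, 1).")
  for (s in config$scales) check_ssf(s)
  config$seed <- as.integer(config$seed)
  structure(config, class = c("texsurv_config", "list"))
}

# hash of the scientific configuration only: file-system locations do not
# affect results, so they are excluded to keep reruns byte-comparable
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  cfg$paths <- NULL
  rlang::hash(cfg)
}

# CSV writer with a provenance header comment (config hash + seed)
write_result_table <- function(x, path, config) {
  writeLines(sprintf("# texsurv %s config_hash=%s seed=%d",
                     as.character(utils::packageVersion("texsurv")),
                     config_hash(config), config$seed),
             path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read a result/feature/clinical CSV written by the pipeline
#'
#' @param path CSV path; `#`-prefixed header comments are skipped.
#' @return A tibble.
#' @export
read_result_table <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

as_table <- function(x, what) {
  if (is.null(x)) abort(sprintf("no `%s` supplied (argument or config$paths$%s).", what, what))
  if (is.character(x) && length(x) == 1L) read_result_table(x) else as_tibble(x, .name_repair = "minimal")
}

# deterministic per-subject seed derived from the run seed
derive_seed <- function(seed, i, stream = 0L) {
  as.integer((as.numeric(seed) * 10007 + stream * 1000003 + i) %% 2147483647)
}

#' Batch feature extraction stage
#'
#' Runs [extract_features()] over a manifest of image/mask pairs and, when
#' `config$out_dir` is set, writes `features.csv` with a provenance
#' header. Per-subject failures are logged and recorded, never silently
#' dropped; the run fails only if every subject fails.
#'
#' @param manifest Data frame or CSV path with columns `subject_id`,
#'   `image`, `mask` (and optionally `spacing`); defaults to
#'   `config$paths$manifest`.
#' @param config A [run_config()].
#' @return The feature tibble (exclusions in attribute `"exclusions"`).
#' @export
run_extract <- function(manifest = NULL, config = run_config()) {
  manifest <- as_table(manifest %||% config$paths$manifest, "manifest")
  feats <- extract_features(manifest, scales = config$scales,
                            bin_width = config$bin_width)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(feats, file.path(config$out_dir, "features.csv"), config)
    excl <- attr(feats, "exclusions")
    if (!is.null(excl) && nrow(excl)) {
      write_result_table(excl, file.path(config$out_dir, "exclusions.csv"), config)
    }
  }
  feats
}

#' Survival-analysis stage
#'
#' Reproduces the full inference chain on a feature table joined to a
#' clinical table: (a) per-feature, per-scale comparison between survivors
#' and non-survivors (Mann-Whitney); (b) ROC optimal cutoffs with AUC for
#' the features at `config$cutoff_ssf`; (c) Kaplan-Meier curves and
#' log-rank tests for each dichotomized feature; (d) univariate Cox models
#' for clinical variables and for the dichotomized features; (e) bivariate
#' Cox models (feature group + M stage); (f) Spearman collinearity of the
#' features. Degenerate analyses (empty group, constant covariate) appear
#' as flagged rows with a `note`, never as silent omissions.
#'
#' @param features Feature table (or CSV path): `subject_id`, `ssf`,
#'   feature columns. A table without `ssf` is treated as unfiltered
#'   (SSF 0).
#' @param clinical Clinical table (or CSV path): `subject_id`,
#'   `os_months`, `event`, `m_stage` and any clinical covariates.
#' @param config A [run_config()].
#' @return A named list of tibbles: `feature_comparison`, `cutoffs`,
#'   `km_curves`, `logrank`, `clinical_cox`, `feature_cox`,
#'   `bivariate_cox`, `spearman`. Written as CSVs under `config$out_dir`
#'   when set (`table1_clinical_cox.csv`, `table2_feature_comparison.csv`,
#'   `table3_feature_cox.csv`, `table4_bivariate_cox.csv`, `cutoffs.csv`,
#'   `logrank.csv`, `spearman.csv`, `km_<feature>.csv`).
#' @export
run_survival <- function(features = NULL, clinical = NULL, config = run_config()) {
  features <- as_table(features %||% config$paths$features, "features")
  clinical <- as_table(clinical %||% config$paths$clinical, "clinical")
  check_cols(clinical, c("subject_id", "os_months", "event"))
  check_cols(features, "subject_id")
  if (!"ssf" %in% names(features)) features$ssf <- 0

  overlap <- mean(unique(features$subject_id) %in% clinical$subject_id)
  if (overlap < 0.8) {
    abort(sprintf("only %.0f%% of feature subjects found in the clinical table (need >= 80%%).",
                  100 * overlap))
  }

  feature_cols <- intersect(config$features, names(features))
  if (!length(feature_cols)) abort("none of `config$features` found in the feature table.")
  joined <- dplyr::inner_join(features, clinical, by = "subject_id",
                              suffix = c("", ".clin"))

  # (a) survivors vs non-survivors, all scales
  all_feats <- intersect(c("mean", "sd", "mpp", "entropy", "skewness", "kurtosis",
                           config$features), names(features))
  comparison <- compare_by_survival(joined, features = all_feats)

  # features at the dichotomization scale
  at_scale <- joined[joined$ssf == config$cutoff_ssf, , drop = FALSE]
  if (!nrow(at_scale)) {
    abort(sprintf("no features at cutoff_ssf = %g.", config$cutoff_ssf))
  }

  # (b) optimal cutoffs
  cutoffs <- feature_cutoffs(at_scale, features = feature_cols,
                             direction = config$direction)

  # (c) KM + log-rank, (d2) univariate Cox, (e) bivariate Cox per feature
  km_list <- list(); logrank_rows <- list()
  fcox_rows <- list(); bicox_rows <- list()
  for (i in seq_len(nrow(cutoffs))) {
    f <- cutoffs$feature[i]
    dich <- suppressWarnings(dichotomize(at_scale, f, cutoffs$cutoff[i]))
    counts <- attr(dich, "group_counts")
    label_low <- sprintf("<%.4g", cutoffs$cutoff[i])
    label_high <- sprintf(">=%.4g", cutoffs$cutoff[i])
    if (isTRUE(attr(dich, "degenerate"))) {
      note <- "degenerate dichotomization: empty group"
      logrank_rows[[f]] <- tibble(feature = f, chi_square = NA_real_, df = 1L,
                                  p_value = NA_real_, note = note)
      fcox_rows[[f]] <- tibble(feature = f, level = label_low, n = unname(counts["low"]),
                               hazard_ratio = NA_real_, conf_low = NA_real_,
                               conf_high = NA_real_, p_value = NA_real_, note = note)
      next
    }
    km <- km_curve(dich, os_months, event, group)
    km_list[[f]] <- dplyr::mutate(tidy(km), feature = f, .before = 1)
    lr <- logrank_test(dich, os_months, event, group)
    logrank_rows[[f]] <- dplyr::mutate(lr, feature = f, .before = 1)

    fcox_rows[[f]] <- cox_rows_for(dich, "group", config,
                                   feature = f, labels = c(label_high, label_low))
    if ("m_stage" %in% names(dich) && length(unique(dich$m_stage)) > 1) {
      bi <- cox_rows_for(dich, c("m_stage", "group"), config, feature = f,
                         labels = c(label_high, label_low))
      bicox_rows[[f]] <- bi
    } else {
      bicox_rows[[f]] <- tibble(feature = f, term = "m_stage", level = NA_character_,
                                n = NA_integer_, hazard_ratio = NA_real_,
                                conf_low = NA_real_, conf_high = NA_real_,
                                p_value = NA_real_,
                                note = "M stage unavailable or constant")
    }
  }

  # (d1) univariate Cox for clinical covariates
  clin_vars <- intersect(
    c("age_group", "n_stage", "m_stage", "er", "pr", "her2", "subtype",
      "neoadjuvant_ct", "adjuvant_ct", "adjuvant_rt"),
    names(clinical)
  )
  clinical_cox <- purrr::map_dfr(clin_vars, function(cv) {
    res <- tryCatch(
      cox_rows_for(clinical, cv, config),
      error = function(e) tibble(term = cv, level = NA_character_, n = NA_integer_,
                                 hazard_ratio = NA_real_, conf_low = NA_real_,
                                 conf_high = NA_real_, p_value = NA_real_,
                                 note = conditionMessage(e))
    )
    res
  })

  # (f) collinearity at the cutoff scale (needs two or more features)
  spearman <- if (length(all_feats) >= 2) {
    spearman_matrix(at_scale, features = all_feats)
  } else {
    tibble(feature_a = character(), feature_b = character(), rho = numeric(),
           p_value = numeric(), n = integer(), degenerate = logical())
  }

  feature_cox <- dplyr::bind_rows(fcox_rows)
  bivariate_cox <- dplyr::bind_rows(bicox_rows)
  logrank <- dplyr::bind_rows(logrank_rows)

  if (config$p_adjust == "holm") {
    comparison$p_adjusted <- stats::p.adjust(comparison$p_value, "holm")
    logrank$p_adjusted <- stats::p.adjust(logrank$p_value, "holm")
  }

  results <- list(
    feature_comparison = comparison,
    cutoffs = cutoffs,
    km_curves = dplyr::bind_rows(km_list),
    logrank = logrank,
    clinical_cox = clinical_cox,
    feature_cox = feature_cox,
    bivariate_cox = bivariate_cox,
    spearman = spearman
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(clinical_cox, file.path(config$out_dir, "table1_clinical_cox.csv"), config)
    write_result_table(comparison, file.path(config$out_dir, "table2_feature_comparison.csv"), config)
    write_result_table(feature_cox, file.path(config$out_dir, "table3_feature_cox.csv"), config)
    write_result_table(bivariate_cox, file.path(config$out_dir, "table4_bivariate_cox.csv"), config)
    write_result_table(cutoffs, file.path(config$out_dir, "cutoffs.csv"), config)
    write_result_table(logrank, file.path(config$out_dir, "logrank.csv"), config)
    write_result_table(spearman, file.path(config$out_dir, "spearman.csv"), config)
    for (f in names(km_list)) {
      write_result_table(km_list[[f]], file.path(config$out_dir, sprintf("km_%s.csv", f)), config)
    }
  }
  results
}

# univariate/bivariate Cox results in long "variable, level, n, HR, CI, p" form
cox_rows_for <- function(data, covariates, config, feature = NULL, labels = NULL) {
  dat <- data
  for (cv in covariates) {
    if (!is.numeric(dat[[cv]]) || all(dat[[cv]] %in% c(0, 1))) {
      dat[[cv]] <- factor(dat[[cv]])
    }
  }
  fit <- cox_fit(dat, os_months, event, covariates, ties = config$cox_ties)
  td <- tidy(fit)
  rows <- purrr::map_dfr(covariates, function(cv) {
    lv <- levels(factor(dat[[cv]]))
    purrr::map_dfr(seq_along(lv), function(j) {
      n_level <- sum(dat[[cv]] == lv[j], na.rm = TRUE)
      if (j == 1L) {
        tibble(term = cv, level = as.character(lv[j]), n = n_level,
               hazard_ratio = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
               p_value = NA_real_, note = "reference")
      } else {
        term_name <- paste0(cv, lv[j])
        hit <- td[td$term == term_name | td$term == sprintf("`%s`%s", cv, lv[j]), ]
        tibble(term = cv, level = as.character(lv[j]), n = n_level,
               hazard_ratio = hit$hazard_ratio, conf_low = hit$conf_low,
               conf_high = hit$conf_high, p_value = hit$p_value,
               note = if (fit$monotone) "monotone likelihood" else NA_character_)
      }
    })
  })
  if (!is.null(labels) && "group" %in% covariates) {
    rows$level[rows$term == "group"] <- labels[match(
      rows$level[rows$term == "group"], c("high", "low"))]
  }
  if (!is.null(feature)) rows <- dplyr::mutate(rows, feature = feature, .before = 1)
  rows
}

#' Reader-agreement stage
#'
#' Computes per-feature, per-scale intraclass correlation coefficients and
#' qualitative agreement bands between two feature tables (two readers, or
#' repeat readings).
#'
#' @param reading_a,reading_b Feature tables or CSV paths.
#' @param config A [run_config()].
#' @return The ICC tibble; written to `icc.csv` when `config$out_dir` is
#'   set.
#' @export
run_agreement <- function(reading_a = NULL, reading_b = NULL, config = run_config()) {
  a <- as_table(reading_a %||% config$paths$reading_a, "reading_a")
  b <- as_table(reading_b %||% config$paths$reading_b, "reading_b")
  out <- icc_table(a, b, type = config$icc_type)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(out, file.path(config$out_dir, "icc.csv"), config)
  }
  out
}

#' Simulate phantoms tied to a cohort's ground-truth groups
#'
#' Generates one tumor phantom per cohort subject, with the necrotic-core
#' extent depending on the subject's prognostic group (`core_fraction_low`
#' for the elevated-hazard "low-feature" group, i.e. more necrosis and
#' hence lower mean attenuation and MPP; `core_fraction_high` otherwise).
#' Per-subject seeds derive deterministically from `config$seed`.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param config A [run_config()].
#' @return A named list of `texsurv_phantom` objects keyed by subject id.
#' @export
simulate_phantoms <- function(cohort, config = run_config()) {
  phantoms <- purrr::map(seq_len(nrow(cohort)), function(i) {
    cf <- if (cohort$true_group[i] == "low") config$core_fraction_low else config$core_fraction_high
    args <- config$phantom
    args$core_fraction <- cf
    args$seed <- derive_seed(config$seed, i)
    generate_phantom(do.call(phantom_spec, args))
  })
  stats::setNames(phantoms, cohort$subject_id)
}

#' Run the whole study replica on synthetic data
#'
#' End-to-end orchestration: simulate a survival cohort, render one tumor
#' phantom per subject (necrotic-core extent tied to the subject's
#' ground-truth risk group), extract texture features, emulate a second
#' reader by re-drawing each ROI with a jittered radius, then run the
#' survival stage and the agreement stage. Deterministic given
#' `config$seed`; with `out_dir` set, all result tables are written as
#' CSVs with provenance headers.
#'
#' @param config A [run_config()].
#' @return A list: `cohort`, `features`, `features_b`, `survival`
#'   (list of tables, see [run_survival()]), `icc`.
#' @export
run_all <- function(config = run_config()) {
  cohort_args <- utils::modifyList(
    list(n_subjects = config$n_subjects, seed = config$seed),
    config$cohort
  )
  cohort <- generate_cohort(do.call(cohort_spec, cohort_args))
  phantoms <- simulate_phantoms(cohort, config)

  features <- purrr::imap_dfr(phantoms, function(ph, sid) {
    dplyr::bind_cols(
      tibble(subject_id = sid),
      texture_features(ph, scales = config$scales, bin_width = config$bin_width)
    )
  })

  # second reader: same image, ROI radius jittered by +/- reader_jitter
  features_b <- purrr::imap_dfr(phantoms, function(ph, sid) {
    i <- match(sid, cohort$subject_id)
    jitter <- withr::with_seed(derive_seed(config$seed, i, stream = 1L),
                               runif(1, 1 - config$reader_jitter, 1 + config$reader_jitter))
    spec_b <- ph$spec
    n <- spec_b$grid_size
    centre <- (n + 1) / 2
    ax <- (seq_len(n) - centre) * spec_b$pixel_spacing
    d2 <- outer(ax^2, ax^2, "+")
    mask_b <- d2 <= (spec_b$tumor_radius * jitter)^2
    dplyr::bind_cols(
      tibble(subject_id = sid),
      texture_features(ph$image, mask_b, ph$spacing,
                       scales = config$scales, bin_width = config$bin_width)
    )
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_table(cohort, file.path(config$out_dir, "cohort.csv"), config)
    write_result_table(features, file.path(config$out_dir, "features.csv"), config)
    write_result_table(features_b, file.path(config$out_dir, "features_reader_b.csv"), config)
  }

  surv <- run_survival(features, cohort, config)
  agreement <- run_agreement(features, features_b, config)

  list(cohort = cohort, features = features, features_b = features_b,
       survival = surv, icc = agreement)
}
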