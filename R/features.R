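#' First-order filtration-histogram texture features
#'
#' Computes the six histogram statistics of the filtration-histogram
#' technique over a region of interest, at one or more spatial scales. For
#' each scale the whole image is band-pass filtered with [filter_image()]
#' (SSF 0 leaves it untouched), then statistics are taken over the masked
#' pixels:
#'
#' * `mean` — average value (HU at SSF 0, filter response otherwise);
#' * `sd` — sample standard deviation (n - 1 denominator);
#' * `mpp` — mean of positive pixels, i.e. the average of values strictly
#'   greater than zero; `NA` (with a warning) when no pixel is positive;
#' * `entropy` — \eqn{-\sum_i p_i \log_2 p_i} over histogram bins of width
#'   `bin_width` HU (values are assigned to bins by rounding to the nearest
#'   bin centre); empty bins are excluded;
#' * `skewness` — \eqn{g_1 = m_3 / m_2^{3/2}} from population central
#'   moments;
#' * `kurtosis` — excess kurtosis \eqn{g_2 = m_4 / m_2^2 - 3}.
#'
#' When all masked pixels are identical (\eqn{m_2 = 0}), skewness and
#' kurtosis are undefined and returned as `NA` with a warning — never
#' silently zeroed.
#'
#' @param image Numeric HU matrix, or a `texsurv_phantom` (in which case
#'   `mask` and `spacing` default to the phantom's own).
#' @param mask Logical/0-1 matrix congruent with `image`; at least 9 pixels
#'   must be included.
#' @param spacing Isotropic pixel size, mm/pixel.
#' @param scales Numeric vector of SSF scales (0 and/or values in
#'   `[2, 6]` mm). Default: unfiltered plus fine (2 mm), medium (3-5 mm)
#'   and coarse (6 mm).
#' @param bin_width Histogram bin width for the entropy estimate, HU.
#'
#' @return A tibble with one row per scale: `ssf`, `mean`, `sd`, `mpp`,
#'   `entropy`, `skewness`, `kurtosis`, `n_pixels`, `n_positive`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(noise_sd = 0, core_fraction = 0))
#' texture_features(ph, scales = 0)
texture_features <- function(image, mask = NULL, spacing = NULL,
                             scales = c(0, 2, 3, 4, 5, 6),
                             bin_width = 1) {
  if (inherits(image, "texsurv_phantom")) {
    if (is.null(mask)) mask <- image$mask
    if (is.null(spacing)) spacing <- image$spacing
    image <- image$image
  }
  check_image(image)
  mask <- check_mask(mask, image)
  if (sum(mask) < 9) {
    abort(sprintf("ROI too small: %d masked pixels (minimum 9).", sum(mask)))
  }
  if (!length(scales)) abort("`scales` must contain at least one SSF value.")
  if (bin_width <= 0) abort("`bin_width` must be positive.")

  purrr::map_dfr(scales, function(ssf) {
    filtered <- filter_image(image, ssf, spacing)
    vals <- filtered[mask]
    stats <- histogram_stats(vals, bin_width = bin_width)
    tibble(ssf = ssf, !!!stats)
  })
}

# the six first-order statistics on a vector of masked pixel values
histogram_stats <- function(vals, bin_width = 1) {
  n <- length(vals)
  mu <- mean(vals)
  pos <- vals[vals > 0]
  mpp <- if (length(pos) >= 1L) mean(pos) else {
    warn("no positive pixels in ROI; MPP is undefined (NA).")
    NA_real_
  }

  bins <- round(vals / bin_width)
  p <- tabulate(match(bins, unique(bins)))
  p <- p / n
  entropy <- -sum(p * log2(p))

  m2 <- mean((vals - mu)^2)
  if (m2 > 0) {
    skewness <- mean((vals - mu)^3) / m2^1.5
    kurtosis <- mean((vals - mu)^4) / m2^2 - 3
  } else {
    warn("all masked pixels identical; skewness and kurtosis are undefined (NA).")
    skewness <- NA_real_
    kurtosis <- NA_real_
  }

  list(
    mean = mu,
    sd = stats::sd(vals),
    mpp = mpp,
    entropy = entropy,
    skewness = skewness,
    kurtosis = kurtosis,
    n_pixels = n,
    n_positive = length(pos)
  )
}

#' Extract texture features for a batch of image/mask pairs
#'
#' Applies [texture_features()] to every row of a manifest. Subjects whose
#' image or mask fails to load or validate are skipped with a logged error
#' record rather than aborting the batch.
#'
#' @param manifest Data frame with columns `subject_id`, `image`, `mask`
#'   (file paths), and optionally `spacing` (used for formats without
#'   embedded spacing).
#' @param scales SSF scales, as in [texture_features()].
#' @param bin_width Entropy bin width, HU.
#'
#' @return A tibble with one row per subject per scale (`subject_id` +
#'   feature columns). Exclusions are reported as a tibble in the
#'   `"exclusions"` attribute and via messages.
#' @export
extract_features <- function(manifest, scales = c(0, 2, 3, 4, 5, 6),
                             bin_width = 1) {
  check_cols(manifest, c("subject_id", "image", "mask"))
  results <- list()
  exclusions <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[[i]]
    res <- tryCatch({
      sp <- if ("spacing" %in% names(manifest)) manifest$spacing[[i]] else NULL
      img <- read_image(manifest$image[[i]], spacing = sp)
      msk <- read_mask(manifest$mask[[i]])
      feats <- texture_features(img$image, msk, img$spacing,
                                scales = scales, bin_width = bin_width)
      dplyr::bind_cols(tibble(subject_id = sid), feats)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("excluding subject %s: %s", sid, conditionMessage(res)))
      exclusions[[length(exclusions) + 1L]] <-
        tibble(subject_id = sid, reason = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  if (!length(results) && nrow(manifest)) {
    abort("feature extraction failed for every subject.")
  }
  out <- dplyr::bind_rows(results)
  attr(out, "exclusions") <- dplyr::bind_rows(exclusions)
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || all(is.na(a))) b else a
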