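# helper: image whose ROI holds exactly the requested values
image_with_roi <- function(vals) {
  side <- ceiling(sqrt(length(vals)))
  img <- matrix(0, side + 2, side + 2)
  mask <- matrix(FALSE, side + 2, side + 2)
  cells <- cbind(
    1 + ((seq_along(vals) - 1) %% side) + 1,
    1 + ((seq_along(vals) - 1) %/% side) + 1
  )
  img[cells] <- vals
  mask[cells] <- TRUE
  list(image = img, mask = mask)
}

test_that("MPP averages strictly positive pixels only", {
  vals <- rep(c(-2, -1, 1, 3), 3) # 12 pixels, same histogram shape as {-2,-1,1,3}
  x <- image_with_roi(vals)
  tf <- texture_features(x$image, x$mask, spacing = 1, scales = 0)
  expect_equal(tf$mean, 0.25)
  expect_equal(tf$mpp, 2.0)
  expect_equal(tf$n_positive, 6L)
  expect_equal(tf$n_pixels, 12L)
  # the statistic itself on the minimal quartet
  s <- texsurv:::histogram_stats(c(-2, -1, 1, 3))
  expect_equal(s$mean, 0.25)
  expect_equal(s$mpp, 2.0)
  expect_equal(s$n_positive, 2L)
})

test_that("entropy hits the exact uniform and degenerate values", {
  vals <- rep(1:16, each = 4) # 16 equally occupied integer bins
  x <- image_with_roi(vals)
  tf <- texture_features(x$image, x$mask, spacing = 1, scales = 0)
  expect_equal(tf$entropy, 4.0)
  s <- suppressWarnings(texsurv:::histogram_stats(rep(7, 20)))
  expect_equal(s$entropy, 0)
})

test_that("moment statistics match hand computation on {1,2,3,4}", {
  s <- texsurv:::histogram_stats(c(1, 2, 3, 4))
  expect_equal(s$sd, sqrt(5 / 3), tolerance = 1e-12)   # 1.29099...
  expect_equal(s$skewness, 0)
  expect_equal(s$kurtosis, -1.36)
})

test_that("degenerate ROIs are flagged with NA, never silently zeroed", {
  warns <- testthat::capture_warnings(s <- texsurv:::histogram_stats(rep(-5, 12)))
  expect_match(warns, "positive|identical", all = TRUE)
  expect_length(warns, 2L)
  expect_true(is.na(s$mpp))
  expect_true(is.na(s$skewness))
  expect_true(is.na(s$kurtosis))
  expect_equal(s$sd, 0)
})

test_that("ROI below 9 pixels or mismatched mask is rejected", {
  img <- matrix(1, 10, 10)
  small_mask <- matrix(FALSE, 10, 10); small_mask[1:8] <- TRUE
  expect_error(texture_features(img, small_mask, 1, scales = 0), "ROI too small")
  expect_error(texture_features(img, matrix(TRUE, 9, 9), 1, scales = 0),
               "same dimensions")
})

test_that("unfiltered statistics shift correctly under a constant offset", {
  vals <- withr::with_seed(2, round(rnorm(100, 50, 10)))
  x <- image_with_roi(vals)
  base <- texture_features(x$image, x$mask, 1, scales = 0)
  shifted <- texture_features(x$image + 7, x$mask, 1, scales = 0)
  expect_equal(shifted$mean, base$mean + 7)
  expect_equal(shifted$mpp, base$mpp + 7) # all ROI pixels positive in both
  expect_equal(shifted$sd, base$sd)
  expect_equal(shifted$skewness, base$skewness)
  expect_equal(shifted$kurtosis, base$kurtosis)
  expect_equal(shifted$entropy, base$entropy) # integer shift moves bins rigidly
})

test_that("filtered statistics are invariant to constant offsets", {
  ph <- generate_phantom(phantom_spec(grid_size = 64, tumor_radius = 15,
                                      pixel_spacing = 1, noise_sd = 10, seed = 3))
  base <- texture_features(ph$image, ph$mask, 1, scales = c(2, 4, 6))
  shifted <- texture_features(ph$image + 300, ph$mask, 1, scales = c(2, 4, 6))
  for (col in c("mean", "sd", "mpp", "entropy", "skewness", "kurtosis")) {
    expect_equal(shifted[[col]], base[[col]], tolerance = 1e-6)
  }
})

test_that("entropy is bounded by log2 of occupied bins, with equality at uniformity", {
  for (seed in 1:5) {
    vals <- withr::with_seed(seed, sample(0:30, 60, replace = TRUE))
    s <- texsurv:::histogram_stats(vals)
    n_bins <- length(unique(round(vals)))
    expect_lte(s$entropy, log2(n_bins) + 1e-12)
  }
  uniform <- rep(1:8, each = 5)
  expect_equal(texsurv:::histogram_stats(uniform)$entropy, 3)
})

test_that("a constant image filters to zero-valued features with undefined MPP", {
  const <- matrix(50, 48, 48)
  mask <- matrix(FALSE, 48, 48); mask[20:28, 20:28] <- TRUE
  tf <- suppressWarnings(texture_features(const, mask, 1, scales = c(0, 2, 6)))
  filtered <- tf[tf$ssf > 0, ]
  expect_equal(filtered$mean, c(0, 0), tolerance = 1e-9)
  expect_equal(filtered$sd, c(0, 0), tolerance = 1e-9)
  expect_equal(filtered$n_positive, c(0L, 0L))
  expect_true(all(is.na(filtered$mpp)))
})

test_that("feature rows come back in the order scales were requested", {
  ph <- generate_phantom(phantom_spec(grid_size = 64, tumor_radius = 15,
                                      pixel_spacing = 1, noise_sd = 5, seed = 8))
  tf <- texture_features(ph, scales = c(6, 0, 3))
  expect_equal(tf$ssf, c(6, 0, 3))
  expect_equal(nrow(tf), 3L)
})

test_that("necrotic-core growth strictly lowers the unfiltered masked mean", {
  means <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(cf) {
    ph <- generate_phantom(phantom_spec(noise_sd = 0, core_fraction = cf))
    suppressWarnings(texture_features(ph, scales = 0)$mean)
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})
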