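# internal helpers shared across modules

# validate an SSF scale value: 0 (no filtration) or a radius in [2, 6] mm
check_ssf <- function(ssf) {
  if (!is.numeric(ssf) || length(ssf) != 1L || !is.finite(ssf)) {
    abort("`ssf` must be a single finite number.")
  }
  if (ssf != 0 && (ssf < 2 || ssf > 6)) {
    abort(sprintf(
      "`ssf` must be 0 (no filtration) or a spatial scale in [2, 6] mm, got %g.",
      ssf
    ))
  }
  ssf
}

check_spacing <- function(spacing) {
  if (!is.numeric(spacing) || !length(spacing) %in% c(1L, 2L) ||
      any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be a positive pixel size in mm/pixel.")
  }
  if (length(spacing) == 2L && abs(spacing[1] - spacing[2]) > 1e-9 * spacing[1]) {
    abort("anisotropic in-plane pixel spacing is not supported; resample the image first.")
  }
  spacing[1]
}

check_image <- function(img, arg = "image") {
  if (!is.matrix(img) || !is.numeric(img) || any(dim(img) < 1L)) {
    abort(sprintf("`%s` must be a non-empty numeric matrix.", arg))
  }
  if (any(!is.finite(img))) {
    abort(sprintf("`%s` contains non-finite pixel values.", arg))
  }
  img
}

check_mask <- function(mask, img) {
  if (!is.matrix(mask) || !identical(dim(mask), dim(img))) {
    abort("`mask` must be a matrix with the same dimensions as the image.")
  }
  m <- mask > 0.5
  if (any(is.na(m))) abort("`mask` contains missing values.")
  m
}

check_flag <- function(x, arg) {
  if (!is.numeric(x) && !is.logical(x)) {
    abort(sprintf("`%s` must be numeric or logical.", arg))
  }
  invisible(x)
}

# column presence check for data-frame-first interfaces
check_cols <- function(data, cols) {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("column(s) not found in `data`: %s", paste(missing, collapse = ", ")))
  }
  invisible(data)
}
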