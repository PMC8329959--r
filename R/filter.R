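#' Discrete Laplacian-of-Gaussian band-pass kernel
#'
#' Builds the 2D LoG kernel used by the filtration-histogram technique. The
#' spatial scale `ssf` (mm) is the radius of the image structures the
#' band-pass highlights; it is mapped to the Gaussian width by setting the
#' kernel's zero-crossing radius equal to `ssf`, i.e.
#' \eqn{\sigma = \mathrm{ssf}/\sqrt{2}} mm. Entries are the continuous LoG
#' \deqn{-\frac{1}{\pi\sigma^4}\Bigl(1 - \frac{r^2}{2\sigma^2}\Bigr)
#'       e^{-r^2/(2\sigma^2)}}
#' evaluated at pixel centres (r in mm), truncated at \eqn{4\sigma}, then
#' shifted by a constant so the entries sum to exactly zero. Zero DC gain
#' guarantees a constant image filters to zero, so filtered statistics are
#' invariant to adding a constant to the input.
#'
#' @param ssf Spatial scale in mm, in `[2, 6]`. SSF 0 means no filtration
#'   and has no kernel; requesting one is an error.
#' @param spacing Isotropic pixel size, mm/pixel.
#'
#' @return A square numeric matrix of odd side length with attributes
#'   `sigma_mm` and `radius_px`.
#' @export
#' @examples
#' k <- log_kernel(2, spacing = 0.7)
#' sum(k)  # 0 by construction
log_kernel <- function(ssf, spacing) {
  check_ssf(ssf)
  spacing <- check_spacing(spacing)
  if (ssf == 0) {
    abort("SSF 0 denotes no filtration; there is no kernel at scale 0.")
  }
  sigma <- ssf / sqrt(2)                  # mm; zero crossing at r = ssf
  radius_px <- as.integer(ceiling(4 * sigma / spacing))
  offsets <- seq(-radius_px, radius_px) * spacing
  r2 <- outer(offsets^2, offsets^2, "+")  # mm^2
  k <- -1 / (pi * sigma^4) * (1 - r2 / (2 * sigma^2)) * exp(-r2 / (2 * sigma^2))
  k <- k - mean(k)                        # exact zero DC gain
  attr(k, "sigma_mm") <- sigma
  attr(k, "radius_px") <- radius_px
  k
}

#' Band-pass filter an image at one spatial scale
#'
#' Convolves the full image with the [log_kernel()] for scale `ssf`, using
#' symmetric reflection padding at the borders; the output has the same
#' shape as the input. SSF 0 returns the input unchanged (no filtration).
#' The whole image is filtered before any masking so ROI statistics are
#' free of artificial edges at the ROI boundary.
#'
#' @param image Numeric matrix of HU values (all finite).
#' @param ssf Spatial scale in mm (0 or `[2, 6]`).
#' @param spacing Isotropic pixel size, mm/pixel.
#'
#' @return A numeric matrix of the same dimensions.
#' @export
filter_image <- function(image, ssf, spacing) {
  check_image(image)
  check_ssf(ssf)
  if (ssf == 0) return(image)
  k <- log_kernel(ssf, spacing)
  r <- attr(k, "radius_px")
  if (r >= nrow(image) || r >= ncol(image)) {
    abort(sprintf(
      "image (%d x %d px) is too small for SSF %g mm at %g mm/px (kernel radius %d px).",
      nrow(image), ncol(image), ssf, check_spacing(spacing), r
    ))
  }
  padded <- reflect_pad(image, r)
  full <- conv2_fft(padded, k)
  out <- full[(2 * r + 1):(2 * r + nrow(image)), (2 * r + 1):(2 * r + ncol(image))]
  # snap FFT roundoff to an exact zero so the zero-DC property (constant in,
  # zero out) holds literally; threshold is relative to the input scale
  out[abs(out) < 1e-10 * max(abs(image), 1)] <- 0
  out
}

# symmetric (edge-including) reflection padding by r pixels on every side
reflect_pad <- function(m, r) {
  idx <- function(n) c(r:1, 1:n, n:(n - r + 1))
  m[idx(nrow(m)), idx(ncol(m)), drop = FALSE]
}

# full 2D convolution via FFT; kernel assumed symmetric under 180-degree
# rotation, so convolution and correlation coincide
conv2_fft <- function(x, k) {
  n1 <- nrow(x) + nrow(k) - 1L
  n2 <- ncol(x) + ncol(k) - 1L
  X <- matrix(0, n1, n2); X[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  K <- matrix(0, n1, n2); K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  Re(fft(fft(X) * fft(K), inverse = TRUE)) / (n1 * n2)
}
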