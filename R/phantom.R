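#' Specify a synthetic CT tumor phantom
#'
#' Builds the parameter set for a single-slice tumor phantom: a disc of
#' enhancing tissue (`rim_hu`), an optional concentric hypodense necrotic
#' core (`core_hu`), additive Gaussian noise, and a uniform background. The
#' phantom emulates the post-contrast appearance of an enhancing breast
#' tumor with central low attenuation on chest CT, and is the unit of input
#' for [texture_features()].
#'
#' Default attenuations are chosen to resemble post-contrast soft-tissue
#' tumors: strongly enhancing rim near 100 HU, necrotic core near 20 HU,
#' fatty background below 0 HU.
#'
#' @param grid_size Image side length in pixels (>= 16).
#' @param pixel_spacing Isotropic in-plane pixel size, mm/pixel.
#' @param tumor_radius Tumor disc radius in mm; must fit inside the grid.
#' @param rim_hu Attenuation of the enhancing tissue, HU.
#' @param core_hu Attenuation of the necrotic core, HU.
#' @param core_fraction Fraction of `tumor_radius` occupied by the core,
#'   in `[0, 1)`; 0 disables the core.
#' @param noise_sd Standard deviation of additive Gaussian noise, HU.
#' @param background_hu Attenuation outside the tumor, HU.
#' @param seed Integer seed; all randomness in [generate_phantom()] flows
#'   from it.
#'
#' @return A list of class `phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
#' @examples
#' spec <- phantom_spec(noise_sd = 0, core_fraction = 0)
#' ph <- generate_phantom(spec)
#' mean(ph$image[ph$mask])  # exactly rim_hu
phantom_spec <- function(grid_size = 128L,
                         pixel_spacing = 0.7,
                         tumor_radius = 25,
                         rim_hu = 100,
                         core_hu = 20,
                         core_fraction = 0.4,
                         noise_sd = 10,
                         background_hu = -50,
                         seed = 1L) {
  if (grid_size < 16) abort("`grid_size` must be at least 16 pixels.")
  check_spacing(pixel_spacing)
  if (!is.finite(tumor_radius) || tumor_radius <= 0) {
    abort("`tumor_radius` must be a positive length in mm.")
  }
  if (core_fraction < 0 || core_fraction >= 1) {
    abort("`core_fraction` must lie in [0, 1).")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  half_extent_mm <- grid_size * pixel_spacing / 2
  if (tumor_radius >= half_extent_mm) {
    abort(sprintf(
      "tumor of radius %g mm does not fit inside a %d-pixel grid at %g mm/pixel (half-extent %g mm).",
      tumor_radius, as.integer(grid_size), pixel_spacing, half_extent_mm
    ))
  }
  structure(
    list(
      grid_size = as.integer(grid_size),
      pixel_spacing = pixel_spacing,
      tumor_radius = tumor_radius,
      rim_hu = rim_hu,
      core_hu = core_hu,
      core_fraction = core_fraction,
      noise_sd = noise_sd,
      background_hu = background_hu,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Generate a tumor phantom image and its ROI mask
#'
#' Renders the phantom described by a [phantom_spec()]: background, tumor
#' disc at `rim_hu`, concentric core at `core_hu`, plus additive Gaussian
#' noise truncated to the signed 16-bit range (the valid range of CT raster
#' storage). The region of interest is the full tumor disc, mirroring a
#' manually drawn ROI around the entire enhancing tumor margin.
#'
#' The same spec (including seed) always produces bit-identical output; no
#' global RNG state is consumed.
#'
#' @param spec A [phantom_spec()].
#'
#' @return A list of class `texsurv_phantom` with elements `image` (numeric
#'   matrix, HU), `mask` (logical matrix, the tumor disc), `spacing`
#'   (mm/pixel) and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) {
    spec <- do.call(phantom_spec, as.list(spec))
  }
  n <- spec$grid_size
  centre <- (n + 1) / 2
  ax <- (seq_len(n) - centre) * spec$pixel_spacing
  # squared distance (mm^2) from the grid centre at each pixel centre
  d2 <- outer(ax^2, ax^2, "+")
  mask <- d2 <= spec$tumor_radius^2
  core <- d2 <= (spec$core_fraction * spec$tumor_radius)^2

  img <- matrix(spec$background_hu, n, n)
  img[mask] <- spec$rim_hu
  img[core] <- spec$core_hu

  if (spec$noise_sd > 0) {
    noise <- withr::with_seed(spec$seed, rnorm(n * n, sd = spec$noise_sd))
    img <- img + matrix(noise, n, n)
  }
  img <- pmin(pmax(img, -32768), 32767)

  structure(
    list(image = img, mask = mask, spacing = spec$pixel_spacing, spec = spec),
    class = "texsurv_phantom"
  )
}

#' @export
print.texsurv_phantom <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<texsurv_phantom> %dx%d px @ %.3g mm/px; tumor r=%g mm (core %.0f%%), rim %g HU, core %g HU, noise sd %g HU\n",
    s$grid_size, s$grid_size, s$pixel_spacing, s$tumor_radius,
    100 * s$core_fraction, s$rim_hu, s$core_hu, s$noise_sd
  ))
  invisible(x)
}

#' Plot a phantom slice with its ROI outline
#'
#' @param phantom A `texsurv_phantom`.
#' @param show_mask Overlay the ROI boundary.
#' @return A ggplot object.
#' @export
plot_phantom <- function(phantom, show_mask = TRUE) {
  df <- tidyr::expand_grid(
    row = seq_len(nrow(phantom$image)),
    col = seq_len(ncol(phantom$image))
  )
  df$hu <- as.vector(t(phantom$image))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", name = "HU") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL)
  if (show_mask) {
    edge <- df[as.vector(t(mask_boundary(phantom$mask))), , drop = FALSE]
    p <- p + ggplot2::geom_tile(data = edge, fill = "red", width = 1, height = 1)
  }
  p
}

# boundary pixels of a logical mask (4-neighbourhood)
mask_boundary <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  shrink <- mask
  shrink[2:n, ] <- shrink[2:n, ] & mask[1:(n - 1), ]
  shrink[1:(n - 1), ] <- shrink[1:(n - 1), ] & mask[2:n, ]
  shrink[, 2:m] <- shrink[, 2:m] & mask[, 1:(m - 1)]
  shrink[, 1:(m - 1)] <- shrink[, 1:(m - 1)] & mask[, 2:m]
  mask & !shrink
}
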