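#' Read a single-slice image with pixel spacing
#'
#' Supports NIfTI (`.nii`, `.nii.gz`; spacing taken from the header) and
#' TIFF (`.tif`, `.tiff`; spacing must be supplied or present in a YAML
#' sidecar `<path>.yml` with fields `spacing` and optionally `offset`).
#' TIFF rasters are stored as unsigned 16-bit with an additive intensity
#' offset (default 32768) so that negative HU survive the round trip; the
#' offset is subtracted on read. 3D NIfTI volumes with a singleton third
#' dimension are squeezed to 2D; anything thicker is rejected.
#'
#' @param path Image file path.
#' @param spacing Pixel size in mm/pixel, overriding header/sidecar.
#' @return A list with `image` (numeric matrix) and `spacing` (mm/pixel).
#' @export
read_image <- function(path, spacing = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    vol <- RNifti::readNifti(path)
    arr <- as.array(vol)
    if (length(dim(arr)) == 3L && dim(arr)[3] == 1L) arr <- arr[, , 1L]
    if (length(dim(arr)) != 2L) {
      abort(sprintf("expected a single-slice image, got dimensions %s.",
                    paste(dim(arr), collapse = "x")))
    }
    sp <- spacing %||% RNifti::pixdim(vol)[1:2]
    list(image = matrix(as.numeric(arr), nrow(arr), ncol(arr)),
         spacing = check_spacing(sp))
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    side <- read_sidecar(path)
    sp <- spacing %||% side$spacing
    if (is.null(sp)) {
      abort(sprintf("no pixel spacing for TIFF %s: supply `spacing` or a sidecar.", path))
    }
    offset <- side$offset %||% 0
    list(image = matrix(as.numeric(raw) - offset, nrow(raw), ncol(raw)),
         spacing = check_spacing(sp))
  } else {
    abort(sprintf("unsupported image format: %s (use NIfTI or TIFF).", path))
  }
}

#' Read a binary ROI mask
#'
#' Reads a raster with [read_image()] and binarizes it at 0.5.
#'
#' @inheritParams read_image
#' @return A logical matrix.
#' @export
read_mask <- function(path, spacing = NULL) {
  img <- tryCatch(
    read_image(path, spacing = spacing),
    error = function(e) {
      # masks in TIFF form may lack a sidecar; spacing is irrelevant for them
      if (grepl("no pixel spacing", conditionMessage(e))) {
        read_image(path, spacing = 1)
      } else {
        stop(e)
      }
    }
  )
  img$image > 0.5
}

#' Write a raster as NIfTI or 16-bit TIFF
#'
#' NIfTI output stores rounded signed 16-bit integers with the pixel
#' spacing in the header. TIFF output stores unsigned 16-bit samples with
#' an additive `offset` (so negative HU are representable) and writes a
#' YAML sidecar `<path>.yml` recording `spacing` and `offset`.
#'
#' @param image Numeric matrix (HU) or logical matrix (mask).
#' @param path Output path ending in `.nii`, `.nii.gz`, `.tif` or `.tiff`.
#' @param spacing Pixel size, mm/pixel.
#' @param offset Intensity offset used for TIFF storage.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, spacing, offset = 32768) {
  storage <- round(image)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(
      matrix(as.integer(storage), nrow(storage)),
      reference = list(pixdim = c(0, spacing, spacing, 1, 0, 0, 0, 0)),
      datatype = "int16"
    )
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    vals <- storage + offset
    if (any(vals < 0 | vals > 65535)) {
      abort("image values out of range for offset 16-bit TIFF storage.")
    }
    tiff::writeTIFF(matrix(as.integer(vals), nrow(vals)) / 65535, path,
                    bits.per.sample = 16L)
    yaml::write_yaml(list(spacing = spacing, offset = offset),
                     paste0(path, ".yml"))
  } else {
    abort(sprintf("unsupported output format: %s (use NIfTI or TIFF).", path))
  }
  invisible(path)
}

#' Write a phantom's image and ROI mask to disk
#'
#' @param phantom A `texsurv_phantom`.
#' @param image_path,mask_path Output paths (NIfTI or TIFF).
#' @return A list with the two paths, invisibly.
#' @export
write_phantom <- function(phantom, image_path, mask_path) {
  write_image(phantom$image, image_path, phantom$spacing)
  write_image(phantom$mask * 1, mask_path, phantom$spacing)
  invisible(list(image = image_path, mask = mask_path))
}

read_sidecar <- function(path) {
  side_path <- paste0(path, ".yml")
  if (file.exists(side_path)) yaml::read_yaml(side_path) else list()
}
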