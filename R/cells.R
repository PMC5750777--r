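#' Segmented single-cell image
#'
#' Bundle a grayscale intensity raster with a same-shape label mask that
#' distinguishes background (0), cytoplasm (1) and nucleus (2). This is the
#' raw input unit for feature extraction: segmentation itself (e.g. by CHAMP
#' or any other tool) is assumed to have happened upstream.
#'
#' @param intensity Numeric matrix of pixel intensities in \[0, 255\], or a
#'   3-channel array (height x width x 3) which is converted to grayscale
#'   with the ITU-R BT.601 luma weights (0.299, 0.587, 0.114).
#' @param mask Integer matrix of the same shape with values 0 (background),
#'   1 (cytoplasm), 2 (nucleus).
#' @param pixel_size Optional physical pixel size in micrometres per pixel;
#'   metadata only, never used in computations.
#'
#' @return An object of class `segmented_cell`: a list with elements
#'   `intensity`, `mask` and `pixel_size`.
#'
#' @details The nucleus and cytoplasm regions must both be non-empty; an
#'   empty region is a segmentation failure and raises an error rather than
#'   propagating NaNs into downstream features.
#'
#' @examples
#' mask <- matrix(0L, 32, 32)
#' mask[8:24, 8:24] <- 1L
#' mask[12:20, 12:20] <- 2L
#' img <- matrix(200, 32, 32)
#' img[mask == 2] <- 90
#' cell <- segmented_cell(img, mask)
#' cell
#' @export
segmented_cell <- function(intensity, mask, pixel_size = NULL) {
  if (length(dim(intensity)) == 3L) {
    if (dim(intensity)[3] < 3L)
      stopf("intensity array must have 3 channels to convert to grayscale")
    intensity <- 0.299 * intensity[, , 1] + 0.587 * intensity[, , 2] +
      0.114 * intensity[, , 3]
  }
  if (!is.matrix(intensity)) stopf("intensity must be a matrix")
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  if (!all(dim(intensity) == dim(mask)))
    stopf("intensity (%dx%d) and mask (%dx%d) shapes differ",
          nrow(intensity), ncol(intensity), nrow(mask), ncol(mask))
  storage.mode(mask) <- "integer"
  if (!all(mask %in% 0:2))
    stopf("mask values must be 0 (background), 1 (cytoplasm) or 2 (nucleus)")
  if (!any(mask == 2L)) stopf("nucleus region is empty")
  if (!any(mask == 1L)) stopf("cytoplasm region is empty")
  if (anyNA(intensity)) stopf("intensity contains NA")
  structure(
    list(intensity = intensity, mask = mask, pixel_size = pixel_size),
    class = "segmented_cell"
  )
}

#' @export
print.segmented_cell <- function(x, ...) {
  cat(sprintf("Segmented cell: %d x %d px, nucleus %d px, cytoplasm %d px\n",
              nrow(x$intensity), ncol(x$intensity),
              sum(x$mask == 2L), sum(x$mask == 1L)))
  if (!is.null(x$pixel_size))
    cat(sprintf("  pixel size: %g um/px\n", x$pixel_size))
  invisible(x)
}

#' Read a segmented cell from an image pair
#'
#' Reads an 8-bit intensity image and its label mask from PNG (or TIFF, if
#' the tiff package is installed) files and returns a [segmented_cell()].
#'
#' @param intensity_path Path to the grayscale or RGB intensity image.
#' @param mask_path Path to the label image.
#' @param mask_levels Either the numeric gray values encoding background,
#'   cytoplasm and nucleus in that order (default `c(0, 1, 2)` as written by
#'   [write_cell()]), or, for colour-coded ground-truth masks, a data frame
#'   with columns `r`, `g`, `b` (0-255) and `label` (0/1/2) mapping each
#'   colour to a region label.
#' @param pixel_size Optional micrometres per pixel, stored as metadata.
#' @return A `segmented_cell`.
#' @export
read_cell <- function(intensity_path, mask_path, mask_levels = c(0, 1, 2),
                      pixel_size = NULL) {
  intensity <- read_raster(intensity_path) * 255
  mraw <- read_raster_raw(mask_path)
  if (length(dim(mraw)) == 3L) {
    if (!is.data.frame(mask_levels))
      stopf("mask image is colour-coded; supply a colour table via mask_levels")
    rgb <- round(255 * mraw[, , 1:3])
    key <- rgb[, , 1] * 65536 + rgb[, , 2] * 256 + rgb[, , 3]
    tab_key <- mask_levels$r * 65536 + mask_levels$g * 256 + mask_levels$b
    idx <- match(as.vector(key), tab_key)
    if (anyNA(idx)) stopf("mask contains colours absent from the colour table")
    mask <- matrix(as.integer(mask_levels$label[idx]), nrow(key), ncol(key))
  } else {
    v <- round(255 * mraw)
    mask <- matrix(match(as.vector(v), mask_levels) - 1L, nrow(v), ncol(v))
    if (anyNA(mask))
      stopf("mask gray values do not match mask_levels = {%s}",
            paste(mask_levels, collapse = ", "))
  }
  segmented_cell(intensity, mask, pixel_size = pixel_size)
}

#' Write a segmented cell as an image pair
#'
#' Writes the intensity raster and the 0/1/2 label mask as 8-bit grayscale
#' PNGs. The mask is stored with raw gray values 0, 1, 2 so that
#' [read_cell()] with default `mask_levels` round-trips exactly.
#'
#' @param cell A `segmented_cell`.
#' @param intensity_path,mask_path Output PNG paths.
#' @return Invisibly, the two paths.
#' @export
write_cell <- function(cell, intensity_path, mask_path) {
  stopifnot(inherits(cell, "segmented_cell"))
  png::writePNG(pmin(pmax(cell$intensity, 0), 255) / 255, intensity_path)
  png::writePNG(cell$mask / 255, mask_path)
  invisible(c(intensity_path, mask_path))
}

# Read an image file as numeric in [0,1]; grayscale collapsed to a matrix.
read_raster <- function(path) {
  x <- read_raster_raw(path)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] >= 3L)
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    else
      x <- x[, , 1]
  }
  x
}

read_raster_raw <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stopf("reading TIFF requires the tiff package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
}
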