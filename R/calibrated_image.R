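#' Calibrated RGB histology image
#'
#' Couples an 8-bit RGB pixel array with its physical pixel size
#' (microns per pixel, mpp). All imaging operations in the package take and
#' honour this calibration, so thresholds expressed in microns behave the
#' same at any scan resolution.
#'
#' @param pixels numeric or integer array of dimension `H x W x 3`, values
#'   in `[0, 255]`. Indexing is row-major: `pixels[row, col, channel]`.
#' @param mpp microns per pixel, a single positive number.
#'
#' @return An object of class `calibrated_image`: a list with elements
#'   `pixels` (integer array) and `mpp`.
#' @examples
#' img <- calibrated_image(array(255L, dim = c(4, 4, 3)), mpp = 0.5)
#' dim(img$pixels)
#' @export
calibrated_image <- function(pixels, mpp) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L)
    stop("image must have at least one row and one column", call. = FALSE)
  if (!is.numeric(mpp) || length(mpp) != 1L || !is.finite(mpp) || mpp <= 0)
    stop("`mpp` must be a single positive number", call. = FALSE)
  px <- pixels
  storage.mode(px) <- "integer"
  if (anyNA(px) || min(px) < 0L || max(px) > 255L)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  structure(list(pixels = px, mpp = as.numeric(mpp)),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<calibrated_image> %d x %d px, %.4g um/px (%.3g x %.3g mm)\n",
              d[1], d[2], x$mpp, d[1] * x$mpp / 1000, d[2] * x$mpp / 1000))
  invisible(x)
}

#' Read a calibrated image from PNG or TIFF
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param mpp microns per pixel. Required for PNG (the format has no
#'   reliable calibration tag); for TIFF, taken from the resolution tags
#'   when present and not overridden.
#' @return A [calibrated_image()].
#' @export
read_calibrated_image <- function(path, mpp = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF images", call. = FALSE)
    arr <- tiff::readTIFF(path, info = TRUE)
    if (is.null(mpp)) {
      res <- attr(arr, "x.resolution")  # pixels per cm when unit is "cm"
      unit <- attr(arr, "resolution.unit")
      if (!is.null(res) && !is.null(unit) && identical(unit, "cm"))
        mpp <- 10000 / res
    }
  } else stop("unsupported image format: ", ext, call. = FALSE)
  if (is.null(mpp))
    stop("`mpp` must be supplied when the file carries no calibration",
         call. = FALSE)
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  calibrated_image(round(arr * 255), mpp = mpp)
}

#' Write a calibrated image to PNG or TIFF
#'
#' PNG carries no calibration; the mpp must travel in the manifest. TIFF
#' output records the pixel size in the resolution tags (unit cm).
#'
#' @param image a [calibrated_image()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_calibrated_image <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  arr <- image$pixels / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(arr, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF images", call. = FALSE)
    tiff::writeTIFF(arr, path, resolution = 10000 / image$mpp,
                    resolutionUnit = "cm")
  } else stop("unsupported image format: ", ext, call. = FALSE)
  invisible(path)
}
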