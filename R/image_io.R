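#' Construct a calibrated grayscale plate image
#'
#' Wraps a numeric pixel matrix together with its physical calibration.
#' Intensities are normalised to `[0, 1]`; integer-valued matrices are
#' rescaled by the apparent bit depth (255 for 8-bit, 65535 for 16-bit).
#'
#' @param pixels Numeric matrix of intensities (rows = image rows).
#' @param um_per_pixel Physical calibration in micrometres per pixel.
#'   The imaging protocol this pipeline targets uses 6-7 um/pixel;
#'   the default is 6.5.
#' @return An object of class `worm_image` with fields `pixels` and
#'   `um_per_pixel`.
#' @export
as_worm_image <- function(pixels, um_per_pixel = 6.5) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0L) {
    stop_invalid("pixels must be a non-empty numeric matrix")
  }
  check_number(um_per_pixel, "um_per_pixel", lower = 1e-6)
  px <- pixels
  mx <- suppressWarnings(max(px, na.rm = TRUE))
  if (mx > 1) {
    scale <- if (mx <= 255) 255 else 65535
    px <- px / scale
  }
  structure(list(pixels = px, um_per_pixel = as.numeric(um_per_pixel)),
            class = "worm_image")
}

#' Read a grayscale plate image from TIFF or PNG
#'
#' @param path Path to an 8- or 16-bit grayscale TIFF or PNG file.
#' @param um_per_pixel Calibration in micrometres per pixel (default 6.5).
#' @return A [as_worm_image()] object.
#' @export
read_plate_image <- function(path, um_per_pixel = 6.5) {
  if (!file.exists(path)) stop_invalid("image file not found: ", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) > 2L) {
    if (prod(d[-(1:2)]) != 1L) {
      stop_invalid("only single-channel grayscale images are supported: ", path)
    }
    dim(img) <- d[1:2]
  }
  # EBImage stores images x-by-y; transpose to row-by-column matrices
  as_worm_image(t(as.matrix(EBImage::imageData(img))), um_per_pixel)
}

#' Write a 16-bit label image (one integer label per segmented region)
#'
#' @param labels Integer matrix of region labels (0 = background).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_tiff <- function(labels, path) {
  EBImage::writeImage(EBImage::Image(t(labels / 65535)), path,
                      type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' @export
print.worm_image <- function(x, ...) {
  cat("<worm_image> ", nrow(x$pixels), "x", ncol(x$pixels),
      " px @ ", x$um_per_pixel, " um/px\n", sep = "")
  invisible(x)
}

#' @export
dim.worm_image <- function(x) dim(x$pixels)
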