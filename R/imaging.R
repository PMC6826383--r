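# Image intake and binarization.
#
# All thresholds act on 8-bit grayscale intensities (0 = black stain,
# 255 = white background). Stained structures are dark, so the foreground
# of every mask is the intensity interval [0, T].

#' 8-bit grayscale image with physical pixel size
#'
#' Wraps an integer intensity matrix together with the physical edge length
#' of one pixel in micrometers. All downstream measurements are reported in
#' pixels, with Feret diameters additionally converted to micrometers using
#' `pixel_size_um`.
#'
#' @param x Integer matrix of intensities in `[0, 255]`.
#' @param pixel_size_um Physical size of one pixel edge in micrometers
#'   (default 1.4, the scanner resolution the pipeline is calibrated for).
#' @return An object of class `"gray_image"`: an integer matrix with a
#'   `pixel_size_um` attribute.
#' @export
gray_image <- function(x, pixel_size_um = 1.4) {
  if (!is.matrix(x)) stop("`x` must be a matrix")
  stop_if_not_scalar_number(pixel_size_um, "pixel_size_um")
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0")
  v <- as.vector(x)
  if (anyNA(v) || any(v < 0) || any(v > 255))
    stop("intensities must lie in [0, 255]")
  storage.mode(x) <- "integer"
  structure(x, pixel_size_um = pixel_size_um, class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.3g um/px, intensity range [%d, %d]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

#' Physical pixel size of an image or mask
#' @param x A `gray_image` or `binary_mask`.
#' @return Pixel edge length in micrometers.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps)) 1.4 else ps
}

#' Convert a raster to 8-bit grayscale
#'
#' Single-channel input passes through unchanged (after rescaling from
#' `[0, 1]` if needed); 3-channel RGB input is reduced by the standard
#' luminance weighting `0.299 R + 0.587 G + 0.114 B` and rounded to the
#' nearest integer. Any other channel count is rejected.
#'
#' @param img Numeric matrix (grayscale) or `nrow x ncol x 3` array (RGB).
#'   Values may be on the `[0, 1]` scale (as returned by PNG/TIFF readers)
#'   or already on `[0, 255]`.
#' @param pixel_size_um Micrometers per pixel edge.
#' @return A [gray_image].
#' @export
to_gray8 <- function(img, pixel_size_um = 1.4) {
  if (inherits(img, "gray_image")) return(img)
  scale255 <- function(v) {
    if (is.double(v) && max(v, na.rm = TRUE) <= 1) v * 255 else v
  }
  if (is.matrix(img)) {
    return(gray_image(round(scale255(img)), pixel_size_um))
  }
  if (is.array(img) && length(dim(img)) == 3) {
    nch <- dim(img)[3]
    if (nch == 1) return(gray_image(round(scale255(img[, , 1])), pixel_size_um))
    if (nch != 3) stop(sprintf("unsupported channel count: %d", nch))
    v <- scale255(img)
    lum <- 0.299 * v[, , 1] + 0.587 * v[, , 2] + 0.114 * v[, , 3]
    return(gray_image(round(lum), pixel_size_um))
  }
  stop("`img` must be a matrix or a 3-channel array")
}

#' Read an image file as 8-bit grayscale
#'
#' Reads a PNG or TIFF file (by extension) and converts it with [to_gray8()].
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @inheritParams to_gray8
#' @return A [gray_image].
#' @export
read_gray_image <- function(path, pixel_size_um = 1.4) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format: '%s'", ext))
  )
  to_gray8(img, pixel_size_um)
}

#' Write a grayscale image as 8-bit PNG or TIFF
#'
#' @param img A [gray_image].
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  m <- unclass(img) / 255
  attributes(m) <- list(dim = dim(img))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop(sprintf("unsupported image format: '%s'", ext))
  )
  invisible(path)
}

new_binary_mask <- function(m, threshold, pixel_size_um) {
  structure(m, threshold = threshold, pixel_size_um = pixel_size_um,
            class = c("binary_mask", "matrix"))
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, threshold %.6g, %d foreground px\n",
              nrow(x), ncol(x), attr(x, "threshold"), sum(x)))
  invisible(x)
}

#' Binarize with a fixed intensity threshold
#'
#' Foreground is the dark side: pixels with intensity in `[0, threshold]`,
#' both bounds inclusive (stained structures are dark on a light
#' background). Raising the threshold can therefore only grow the mask.
#'
#' @param img A [gray_image].
#' @param threshold Integer threshold in `[0, 255]`.
#' @return A `"binary_mask"`: logical matrix with `threshold` and
#'   `pixel_size_um` attributes.
#' @export
threshold_fixed <- function(img, threshold) {
  img <- to_gray8(img)
  stop_if_not_scalar_number(threshold, "threshold")
  if (threshold < 0 || threshold > 255)
    stop("`threshold` must lie in [0, 255]")
  m <- unclass(img) <= threshold
  attributes(m) <- list(dim = dim(img))
  new_binary_mask(m, threshold, pixel_size(img))
}

#' Automatic threshold by the isodata (intermeans) algorithm
#'
#' Iterates `T <- (mean(x <= T) + mean(x > T)) / 2` from the global mean to
#' a fixed point, then takes foreground as `[0, T]`. The resulting mask is
#' always identical to [threshold_fixed()] at the returned threshold. The
#' threshold depends only on the tonal histogram, so duplicating the image
#' does not change it.
#'
#' @param img A [gray_image] with at least two distinct intensities.
#' @return A `"binary_mask"`; the selected threshold is in the
#'   `threshold` attribute (see [mask_threshold()]).
#' @export
threshold_auto <- function(img) {
  img <- to_gray8(img)
  x <- as.vector(unclass(img))
  if (min(x) == max(x))
    stop("degenerate image: all intensities identical, no threshold exists")
  t_cur <- mean(x)
  for (i in 1:256) {
    lo <- x <= t_cur
    t_new <- (mean(x[lo]) + mean(x[!lo])) / 2
    if (identical(t_new, t_cur)) break
    t_cur <- t_new
  }
  m <- unclass(img) <= t_cur
  attributes(m) <- list(dim = dim(img))
  new_binary_mask(m, t_cur, pixel_size(img))
}

#' Threshold that produced a mask
#' @param mask A `"binary_mask"`.
#' @return The numeric threshold stored in the mask's provenance.
#' @export
mask_threshold <- function(mask) attr(mask, "threshold")

#' Binarize by mode
#'
#' Dispatcher used by the screening grid: `binarization = "auto"` runs
#' [threshold_auto()], a number runs [threshold_fixed()].
#'
#' @param img A [gray_image].
#' @param binarization `"auto"` or a numeric threshold in `[0, 255]`.
#' @return A `"binary_mask"`.
#' @export
binarize <- function(img, binarization = "auto") {
  if (identical(binarization, "auto")) threshold_auto(img)
  else threshold_fixed(img, as.numeric(binarization))
}
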