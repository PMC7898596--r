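#' Grayscale image container
#'
#' A `gray_image` is a plain numeric matrix (rows x cols) carrying intensities
#' on the 8-bit scale `[0, 255]`, with an optional physical pixel size. Pixel
#' centres sit at integer coordinates `(row, col)`, row-major. All pipeline
#' stages consume and produce this representation; fibres are assumed bright
#' on a dark background once [normalise_polarity()] has run.
#'
#' @param pixels numeric matrix of intensities in `[0, 255]`.
#' @param pixel_size_um optional positive scalar, microns per pixel. When set,
#'   lengths and areas are reported in physical units; otherwise in pixels.
#' @return an object of class `gray_image` (a matrix with attributes).
#' @export
gray_image <- function(pixels, pixel_size_um = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    stop("image must be at least 16x16 pixels")
  if (anyNA(pixels))
    stop("image contains missing values")
  if (min(pixels) < -1e-6 || max(pixels) > 255 + 1e-6)
    stop("intensities must lie in [0, 255]")
  if (!is.null(pixel_size_um)) {
    if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
        pixel_size_um <= 0)
      stop("`pixel_size_um` must be a positive scalar")
  }
  structure(pmin(pmax(pixels, 0), 255),
            pixel_size_um = pixel_size_um,
            class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  ps <- attr(x, "pixel_size_um")
  cat(sprintf("gray_image: %d x %d px, range [%.1f, %.1f]%s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (is.null(ps)) "" else sprintf(", %.4g um/px", ps)))
  invisible(x)
}

pixel_size <- function(img) attr(img, "pixel_size_um")

#' Read an image file as a grayscale raster
#'
#' Reads TIFF, PNG or JPEG (8- or 16-bit; 16-bit is linearly rescaled onto the
#' 8-bit range). RGB images are converted by luminance weighting via
#' [to_grayscale()].
#'
#' @param path path to a TIFF/PNG/JPEG file.
#' @param pixel_size_um optional microns per pixel, attached to the result.
#' @return a [gray_image()].
#' @export
read_gray <- function(path, pixel_size_um = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- EBImage::imageData(EBImage::readImage(path))
  # EBImage stores dim1 = x (columns); transpose into (row, col)
  if (length(dim(arr)) == 2L) {
    m <- t(arr) * 255
    gray_image(m, pixel_size_um = pixel_size_um)
  } else {
    nch <- dim(arr)[3L]
    rgb <- aperm(arr, c(2L, 1L, 3L)) * 255
    if (nch >= 3L) {
      to_grayscale(rgb[, , 1:3, drop = FALSE], pixel_size_um = pixel_size_um)
    } else {
      gray_image(rgb[, , 1L], pixel_size_um = pixel_size_um)
    }
  }
}

#' Read an RGB image file
#'
#' @param path path to a colour TIFF/PNG/JPEG file.
#' @return a rows x cols x 3 numeric array with values in `[0, 255]`.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  arr <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(arr)) != 3L || dim(arr)[3L] < 3L)
    stop("not a colour image: ", path)
  aperm(arr, c(2L, 1L, 3L))[, , 1:3, drop = FALSE] * 255
}

#' Write a grayscale raster or binary mask to PNG/TIFF
#'
#' Masks are written with foreground 255 and background 0.
#'
#' @param x a `gray_image`, numeric matrix on `[0,255]`, or logical mask.
#' @param path output path; format chosen from the file extension
#'   (`.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg`).
#' @return `path`, invisibly.
#' @export
write_gray <- function(x, path) {
  if (is.logical(x)) x <- x * 255
  type <- switch(tolower(tools::file_ext(path)),
                 png = "png", tif = "tiff", tiff = "tiff",
                 jpg = "jpeg", jpeg = "jpeg",
                 stop("unsupported output extension: ", path))
  EBImage::writeImage(EBImage::Image(t(unclass(x) / 255)), path, type = type)
  invisible(path)
}
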