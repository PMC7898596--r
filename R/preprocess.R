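#' Convert an RGB raster to grayscale
#'
#' Luminance-weighted combination (Rec. 601 weights 0.299/0.587/0.114) of the
#' three channels, rescaled onto `[0, 255]`. Inputs on `[0, 1]` are scaled up;
#' single-channel planes pass through unchanged apart from the rescale.
#'
#' @param rgb a rows x cols x 3 numeric array (or a plain matrix, passed
#'   through).
#' @inheritParams gray_image
#' @return a [gray_image()].
#' @export
to_grayscale <- function(rgb, pixel_size_um = NULL) {
  if (is.matrix(rgb)) {
    m <- rgb
  } else {
    d <- dim(rgb)
    if (length(d) != 3L || d[3L] != 3L)
      stop("`rgb` must be a rows x cols x 3 array")
    m <- 0.299 * rgb[, , 1L] + 0.587 * rgb[, , 2L] + 0.114 * rgb[, , 3L]
  }
  if (max(m) <= 1 + 1e-9) m <- m * 255
  gray_image(m, pixel_size_um = pixel_size_um)
}

#' Normalise fibre polarity
#'
#' The pipeline's internal convention is fibres bright on a dark background
#' (as in fluorescence or second-harmonic imaging). Images with dark fibres on
#' a light background (conventional histology) are inverted, `v -> 255 - v`.
#'
#' @param img a [gray_image()].
#' @param dark_lines logical; `TRUE` if fibres are dark on light background.
#' @return a [gray_image()] in canonical polarity.
#' @export
normalise_polarity <- function(img, dark_lines = FALSE) {
  if (isTRUE(dark_lines))
    gray_image(255 - unclass(img), pixel_size_um = pixel_size(img))
  else
    img
}

#' Contrast saturation stretch
#'
#' ImageJ-style "Enhance Contrast": clips `saturation_pct`/2 percent of pixels
#' at each histogram tail and maps the remaining intensity range affinely onto
#' `[0, 255]`. `saturation_pct = 0` is a plain min-max stretch. A constant
#' image is returned unchanged with a warning (the stretch is undefined).
#'
#' @param img a [gray_image()].
#' @param saturation_pct percentage of pixels to saturate, in `[0, 100)`.
#' @return a [gray_image()] spanning `[0, 255]`.
#' @export
contrast_saturate <- function(img, saturation_pct = 0.35) {
  if (!is.numeric(saturation_pct) || saturation_pct < 0 || saturation_pct >= 100)
    stop("`saturation_pct` must lie in [0, 100)")
  v <- as.vector(unclass(img))
  lohi <- stats::quantile(v, c(saturation_pct / 200, 1 - saturation_pct / 200),
                          names = FALSE)
  if (diff(lohi) <= .Machine$double.eps * 255) {
    warning("constant image: contrast stretch undefined, returning unchanged")
    return(img)
  }
  out <- (unclass(img) - lohi[1L]) / (lohi[2L] - lohi[1L]) * 255
  gray_image(pmin(pmax(out, 0), 255), pixel_size_um = pixel_size(img))
}

# optical density of 8-bit intensities; +1 offset avoids log(0)
optical_density <- function(intensity) -log10((intensity + 1) / 256)

OD_MAX <- -log10(1 / 256)  # OD of intensity 0, the darkest representable

#' Estimate stain vectors from reference regions
#'
#' For histochemical stains, three rectangular regions of interest are chosen
#' by the user: one of (nearly) pure matrix stain, one of counterstain, one of
#' background. The mean optical-density vector of each region, normalised to
#' unit length, defines that stain's direction in OD-RGB space
#' (Ruifrok-Johnston colour deconvolution). OD per channel is
#' `-log10((I + 1)/256)`.
#'
#' @param rgb rows x cols x 3 array on `[0, 255]`.
#' @param rois list of three integer vectors `c(row_min, row_max, col_min,
#'   col_max)`; each region must lie inside the image and contain at least 25
#'   pixels.
#' @return a `stain_vectors` object: a 3 x 3 matrix, one unit row vector per
#'   stain.
#' @export
estimate_stain_vectors <- function(rgb, rois) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3L] != 3L)
    stop("`rgb` must be a rows x cols x 3 array")
  if (!is.list(rois) || length(rois) != 3L)
    stop("`rois` must be a list of three c(row_min, row_max, col_min, col_max)")
  vecs <- matrix(0, 3L, 3L)
  for (i in 1:3) {
    r <- rois[[i]]
    if (length(r) != 4L || r[1] < 1 || r[3] < 1 || r[2] > d[1L] || r[4] > d[2L] ||
        r[1] > r[2] || r[3] > r[4])
      stop("ROI ", i, " lies outside the image or is malformed")
    if ((r[2] - r[1] + 1) * (r[4] - r[3] + 1) < 25)
      stop("ROI ", i, " contains fewer than 25 pixels")
    block <- rgb[r[1]:r[2], r[3]:r[4], , drop = FALSE]
    od <- apply(optical_density(block), 3L, mean)
    nrm <- sqrt(sum(od^2))
    if (nrm < 1e-3)
      stop("ROI ", i, " has near-zero optical density (pure white): ",
           "cannot define a stain vector")
    vecs[i, ] <- od / nrm
  }
  structure(vecs, class = "stain_vectors",
            dimnames = list(paste0("stain", 1:3), c("R", "G", "B")))
}

#' Colour deconvolution
#'
#' Projects each pixel's optical-density vector onto the stain basis by
#' inverting the 3 x 3 stain matrix (Ruifrok-Johnston scheme). Negative
#' projections are clamped to zero. Each stain concentration channel is mapped
#' linearly onto `[0, 255]` using the fixed full OD scale `log10(256)`, so
#' channel intensities are comparable across images.
#'
#' @param rgb rows x cols x 3 array on `[0, 255]`.
#' @param vectors a `stain_vectors` matrix (rows = stains, unit OD vectors).
#' @return list of three [gray_image()] channels, one per stain.
#' @export
colour_deconvolve <- function(rgb, vectors) {
  d <- dim(rgb)
  if (length(d) != 3L || d[3L] != 3L)
    stop("`rgb` must be a rows x cols x 3 array")
  M <- unclass(vectors)
  if (!is.matrix(M) || any(dim(M) != 3L)) stop("`vectors` must be 3 x 3")
  # guard against a singular basis, naming the offending pair
  ang <- function(i, j) {
    cc <- abs(sum(M[i, ] * M[j, ]))
    acos(pmin(cc, 1)) * 180 / pi
  }
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  angs <- apply(pairs, 1L, function(p) ang(p[1], p[2]))
  if (abs(det(M)) < 1e-6) {
    k <- which.min(angs)
    stop(sprintf("stain matrix is singular: vectors %d and %d are near-collinear (%.2f deg apart)",
                 pairs[k, 1], pairs[k, 2], angs[k]))
  }
  od <- optical_density(rgb)
  odm <- cbind(as.vector(od[, , 1L]), as.vector(od[, , 2L]), as.vector(od[, , 3L]))
  conc <- odm %*% solve(M)        # OD = conc %*% M  =>  conc = OD %*% M^-1
  conc[conc < 0] <- 0
  lapply(1:3, function(i) {
    ch <- matrix(conc[, i], d[1L], d[2L])
    gray_image(pmin(ch / OD_MAX, 1) * 255)
  })
}

#' Re-mix deconvolved channels back into optical density
#'
#' Inverse of [colour_deconvolve()] up to the non-negativity clamp; used to
#' check round-trip consistency of a stain basis.
#'
#' @param channels list of three concentration channels on `[0, 255]`.
#' @param vectors the `stain_vectors` matrix used to unmix.
#' @return rows x cols x 3 array of reconstructed optical densities.
#' @export
remix_stains <- function(channels, vectors) {
  conc <- cbind(as.vector(unclass(channels[[1]])),
                as.vector(unclass(channels[[2]])),
                as.vector(unclass(channels[[3]]))) / 255 * OD_MAX
  od <- conc %*% unclass(vectors)
  array(od, c(dim(channels[[1]]), 3L))
}

#' High-density matrix (HDM) fraction
#'
#' The proportion of pixels classified as matrix: those whose intensity, after
#' polarity normalisation and contrast saturation, is at or above
#' `hdm_threshold`. Returns the fraction and the thresholded raster.
#'
#' @param img a [gray_image()], already polarity-normalised and saturated.
#' @param hdm_threshold intensity threshold on the 8-bit scale, or `"otsu"`
#'   for Otsu's automatic threshold.
#' @return list with elements `hdm` (scalar in `[0, 1]`) and `mask` (logical
#'   matrix).
#' @export
compute_hdm <- function(img, hdm_threshold = 185) {
  if (identical(hdm_threshold, "otsu")) {
    hdm_threshold <- EBImage::otsu(EBImage::Image(t(unclass(img) / 255))) * 255
  }
  if (!is.numeric(hdm_threshold) || hdm_threshold < 0 || hdm_threshold > 255)
    stop("`hdm_threshold` must lie in [0, 255] or be \"otsu\"")
  mask <- unclass(img) >= hdm_threshold
  list(hdm = mean(mask), mask = mask)
}
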