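#' Global gradient structure tensor
#'
#' The 2 x 2 tensor `J = [<fx,fx>_w <fx,fy>_w; <fx,fy>_w <fy,fy>_w]`, where
#' `fx` and `fy` are Gaussian-derivative partial derivatives of the image at
#' scale `gradient_sigma` (x = columns, y = rows) and `< , >_w` is the
#' w-weighted inner product over the field of view, with `w` normalised to
#' sum to one. The default weight is uniform over the whole field of view,
#' giving a single global orientation summary; a Gaussian window centred on a
#' region of interest can be supplied as a weight matrix instead.
#'
#' @param img a [gray_image()] (or numeric matrix).
#' @param gradient_sigma Gaussian derivative scale, px.
#' @param weight `NULL` for uniform weighting, or a non-negative matrix of
#'   the image's shape.
#' @return object of class `structure_tensor`: list with `jxx`, `jxy`, `jyy`.
#' @export
structure_tensor <- function(img, gradient_sigma = 1, weight = NULL) {
  f <- unclass(img)
  if (min(dim(f)) < 4 * gradient_sigma)
    stop("image smaller than 4 sigma in one dimension")
  k <- gauss_kernels(gradient_sigma)
  fx <- conv2sep(f, k$g, k$gd)   # d/dcol
  fy <- conv2sep(f, k$gd, k$g)   # d/drow
  if (is.null(weight)) {
    w <- 1 / length(f)
    jxx <- sum(fx * fx) * w
    jxy <- sum(fx * fy) * w
    jyy <- sum(fy * fy) * w
  } else {
    if (!all(dim(weight) == dim(f)))
      stop("weight matrix must match the image shape")
    w <- weight / sum(weight)
    jxx <- sum(w * fx * fx)
    jxy <- sum(w * fx * fy)
    jyy <- sum(w * fy * fy)
  }
  structure(list(jxx = jxx, jxy = jxy, jyy = jyy),
            class = "structure_tensor")
}

#' Alignment coherency of a structure tensor
#'
#' `a = (lambda_max - lambda_min) / (lambda_max + lambda_min)` from the
#' tensor eigenvalues: 0 is complete isotropy, 1 perfect alignment. A blank
#' image (zero tensor) is defined as coherency 0.
#'
#' @param J a [structure_tensor()].
#' @return scalar in `[0, 1]`.
#' @export
coherency <- function(J) {
  tr <- J$jxx + J$jyy
  if (tr <= 1e-10) return(0)
  sqrt((J$jxx - J$jyy)^2 + 4 * J$jxy^2) / tr
}

#' Global alignment from an image
#'
#' Convenience composition [structure_tensor()] then [coherency()] with the
#' documented defaults (gradient sigma 1 px, uniform global weight).
#'
#' @inheritParams structure_tensor
#' @return coherency in `[0, 1]`.
#' @export
alignment_from_image <- function(img, gradient_sigma = 1) {
  coherency(structure_tensor(img, gradient_sigma))
}

# occupied-box count at one box side (grid anchored at the origin)
count_boxes <- function(mask, eps) {
  H <- nrow(mask); W <- ncol(mask)
  g1 <- (seq_len(H) - 1L) %/% eps
  g2 <- (seq_len(W) - 1L) %/% eps
  m1 <- rowsum(mask * 1L, g1)
  m2 <- t(rowsum(t(m1), g2))
  sum(m2 > 0L)
}

#' Box-counting fractal dimension
#'
#' A grid of squares of side `eps` is overlaid on the mask (anchored at the
#' origin) and the number of squares `N(eps)` occupied by foreground is
#' counted, for dyadic sides `eps = 2, 4, 8, ...` up to a quarter of the
#' smaller image dimension (so at least four boxes always span the image).
#' The dimension is the least-squares slope of `log N(eps)` against
#' `log(1/eps)`; for fibre masks in 2-D it lies in `[1, 2]`.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return the fitted dimension, or `NA` for an empty mask.
#' @export
fractal_dimension <- function(mask) {
  if (!any(mask)) return(NA_real_)
  maxeps <- min(dim(mask)) / 4
  eps <- 2
  sizes <- integer(0)
  while (eps <= maxeps) { sizes <- c(sizes, eps); eps <- eps * 2 }
  if (length(sizes) < 2L)
    stop("mask too small for a box-counting fit")
  N <- vapply(sizes, function(e) count_boxes(mask, e), numeric(1))
  unname(stats::coef(stats::lm(log(N) ~ log(1 / sizes)))[2L])
}

# per-box masses for one gliding-box size (stride = half the box side)
gliding_box_masses <- function(mask, size) {
  H <- nrow(mask); W <- ncol(mask)
  stride <- max(1L, size %/% 2L)
  # summed-area table with zero padding row/col
  S <- matrix(0, H + 1L, W + 1L)
  S[-1L, -1L] <- apply(apply(mask * 1, 2L, cumsum), 1L, cumsum) |> t()
  r0 <- seq(1L, H - size + 1L, by = stride)
  c0 <- seq(1L, W - size + 1L, by = stride)
  as.vector(S[r0 + size, c0 + size, drop = FALSE] -
            S[r0, c0 + size, drop = FALSE] -
            S[r0 + size, c0, drop = FALSE] + S[r0, c0, drop = FALSE])
}

#' Gliding-box lacunarity
#'
#' For each box size a square window glides across the mask (stride half the
#' box side) and the enclosed foreground mass is recorded;
#' `Lambda(size) = |s^2/mu^2 - 1|` from the mean `mu` and standard deviation
#' `s` of the per-box masses, and the mean of `Lambda(size)` over all sizes
#' is returned. Larger values indicate more or larger empty space.
#'
#' Note the absolute-value form assigns a perfectly uniform pattern
#' (`s = 0`) the value 1 and a pattern with `s = mu` the value 0, inverting
#' the conventional gliding-box ordering at the low end;
#' `convention = "plus_one"` gives the conventional `1 + s^2/mu^2` variant.
#'
#' @param mask logical matrix (or numeric matrix for grey-level mode).
#' @param box_sizes integer box sides, each smaller than the smaller image
#'   dimension; default dyadic sizes 4, 8, ... up to a quarter of it.
#' @param convention `"abs"` (default) or `"plus_one"`.
#' @return mean lacunarity over box sizes, with per-size values in attribute
#'   `"by_size"`; `NA` for an all-background mask.
#' @export
lacunarity <- function(mask, box_sizes = NULL,
                       convention = c("abs", "plus_one")) {
  convention <- match.arg(convention)
  if (!any(mask != 0)) return(NA_real_)
  mind <- min(dim(mask))
  if (is.null(box_sizes)) {
    s <- 4L
    box_sizes <- integer(0)
    while (s <= mind / 4) { box_sizes <- c(box_sizes, s); s <- s * 2L }
    if (!length(box_sizes)) box_sizes <- max(2L, mind %/% 4L)
  }
  if (any(box_sizes >= mind))
    stop("box sizes must be smaller than the image")
  by_size <- vapply(box_sizes, function(sz) {
    m <- gliding_box_masses(mask, sz)
    mu <- mean(m)
    if (mu == 0) return(NA_real_)
    s2 <- stats::var(m)
    if (convention == "abs") abs(s2 / mu^2 - 1) else 1 + s2 / mu^2
  }, numeric(1))
  out <- mean(by_size, na.rm = TRUE)
  attr(out, "by_size") <- stats::setNames(by_size, box_sizes)
  out
}
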