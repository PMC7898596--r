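#' Specification of a synthetic fibre scene
#'
#' Describes a parameterised random fibre field with known ground truth,
#' emulating the range of matrix architectures the pipeline targets: aligned
#' anisotropic fields (orientation jitter around a base angle) versus
#' isotropic fields (uniform orientations), with straight, sinusoidal or
#' arc-shaped fibres of controlled width. Rendering is anti-aliased by 4x
#' supersampling so that "width" has a precise geometric meaning for detector
#' validation. A fixed seed gives byte-identical output.
#'
#' @param image_size_px side of the square image, pixels.
#' @param n_fibres number of fibres.
#' @param orientation_mode `"aligned"` or `"isotropic"`.
#' @param base_orientation_deg mean orientation of aligned scenes, degrees.
#' @param jitter_deg s.d. of orientation jitter for aligned scenes, in
#'   `[0, 180]`.
#' @param fibre_width_px fibre width (full thickness), pixels.
#' @param waveform list: `list(type = "straight")`,
#'   `list(type = "sine", amplitude_px =, wavelength_px =)`, or
#'   `list(type = "arc", radius_px =)`.
#' @param length_px fibre length (scalar, or `c(min, max)` range), pixels.
#' @param background_level,fibre_level 8-bit intensities.
#' @param min_separation_px if positive, fibres are rejection-sampled so that
#'   centrelines stay at least this far apart (no crossings).
#' @param noise_sd s.d. of additive Gaussian noise on the 8-bit scale
#'   (0 = none).
#' @param seed integer RNG seed.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_size_px = 256, n_fibres = 30,
                       orientation_mode = c("aligned", "isotropic"),
                       base_orientation_deg = 0, jitter_deg = 5,
                       fibre_width_px = 4,
                       waveform = list(type = "straight"),
                       length_px = NULL,
                       background_level = 10, fibre_level = 200,
                       min_separation_px = 0, noise_sd = 0, seed = 1L) {
  orientation_mode <- match.arg(orientation_mode)
  if (image_size_px < 16) stop("image_size_px must be >= 16")
  if (jitter_deg < 0 || jitter_deg > 180) stop("jitter_deg must lie in [0, 180]")
  if (fibre_width_px <= 0) stop("fibre_width_px must be positive")
  if (is.null(length_px)) length_px <- 0.7 * image_size_px
  structure(list(image_size_px = as.integer(image_size_px),
                 n_fibres = as.integer(n_fibres),
                 orientation_mode = orientation_mode,
                 base_orientation_deg = base_orientation_deg,
                 jitter_deg = jitter_deg,
                 fibre_width_px = fibre_width_px,
                 waveform = waveform, length_px = length_px,
                 background_level = background_level,
                 fibre_level = fibre_level,
                 min_separation_px = min_separation_px,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

# centreline polyline for one fibre, sampled at ~1.5 px spacing
fibre_polyline <- function(centre, theta, len, waveform) {
  u <- c(cos(theta), sin(theta))     # direction (drow, dcol)
  p <- c(-u[2L], u[1L])              # perpendicular
  type <- waveform$type
  if (type == "straight") {
    s <- seq(-len / 2, len / 2, length.out = max(2L, ceiling(len / 1.5) + 1L))
    cbind(centre[1L] + s * u[1L], centre[2L] + s * u[2L])
  } else if (type == "sine") {
    a <- waveform$amplitude_px; wl <- waveform$wavelength_px
    s <- seq(-len / 2, len / 2, length.out = max(8L, ceiling(len / 1.0) + 1L))
    off <- a * sin(2 * pi * s / wl)
    cbind(centre[1L] + s * u[1L] + off * p[1L],
          centre[2L] + s * u[2L] + off * p[2L])
  } else if (type == "arc") {
    r <- waveform$radius_px
    span <- min(len / r, 2 * pi)
    phi <- seq(-span / 2, span / 2,
               length.out = max(8L, ceiling(len / 1.0) + 1L))
    ctr <- centre + r * p              # arc centre offset perpendicular
    cbind(ctr[1L] - r * (cos(phi) * p[1L] - sin(phi) * u[1L]),
          ctr[2L] - r * (cos(phi) * p[2L] - sin(phi) * u[2L]))
  } else stop("unknown waveform type: ", type)
}

# clip polyline to [lo, hi] box; may yield several pieces
clip_polyline <- function(v, lo, hi) {
  inside <- v[, 1L] >= lo & v[, 1L] <= hi & v[, 2L] >= lo & v[, 2L] <= hi
  if (all(inside)) return(list(v))
  pieces <- list()
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in seq_along(runs$values)) {
    if (!runs$values[i]) next
    seg <- v[starts[i]:ends[i], , drop = FALSE]
    if (nrow(seg) >= 2L) pieces[[length(pieces) + 1L]] <- seg
  }
  pieces
}

# count crossings between distinct fibre polylines (segment intersection,
# polylines decimated to ~5 px chords; one count per crossing pair)
count_crossings <- function(polys) {
  dec <- lapply(polys, function(v) {
    idx <- unique(c(seq(1L, nrow(v), by = 4L), nrow(v)))
    v[idx, , drop = FALSE]
  })
  npoly <- length(dec)
  if (npoly < 2L) return(0L)
  bbox <- t(vapply(dec, function(v)
    c(min(v[, 1L]), max(v[, 1L]), min(v[, 2L]), max(v[, 2L])), numeric(4)))
  n <- 0L
  for (a in seq_len(npoly - 1L)) for (b in (a + 1L):npoly) {
    if (bbox[a, 1L] > bbox[b, 2L] || bbox[b, 1L] > bbox[a, 2L] ||
        bbox[a, 3L] > bbox[b, 4L] || bbox[b, 3L] > bbox[a, 4L]) next
    va <- dec[[a]]; vb <- dec[[b]]
    na <- nrow(va) - 1L; nb <- nrow(vb) - 1L
    # segment a: p1 + t (p2 - p1); orientation tests over all pairs at once
    p1r <- va[-nrow(va), 1L]; p1c <- va[-nrow(va), 2L]
    p2r <- va[-1L, 1L];       p2c <- va[-1L, 2L]
    q1r <- vb[-nrow(vb), 1L]; q1c <- vb[-nrow(vb), 2L]
    q2r <- vb[-1L, 1L];       q2c <- vb[-1L, 2L]
    dar <- p2r - p1r; dac <- p2c - p1c
    # cross((p2-p1), (q - p1)) for q = q1, q2
    d1 <- outer(dar, q1c, `*`) - outer(dac, q1r, `*`) -
      matrix(dar * p1c - dac * p1r, na, nb)
    d2 <- outer(dar, q2c, `*`) - outer(dac, q2r, `*`) -
      matrix(dar * p1c - dac * p1r, na, nb)
    dbr <- q2r - q1r; dbc <- q2c - q1c
    d3 <- t(outer(dbr, p1c, `*`) - outer(dbc, p1r, `*`) -
            matrix(dbr * q1c - dbc * q1r, nb, na))
    d4 <- t(outer(dbr, p2c, `*`) - outer(dbc, p2r, `*`) -
            matrix(dbr * q1c - dbc * q1r, nb, na))
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) n <- n + 1L
  }
  n
}

# render polylines of a given width into a grayscale raster, 4x supersampled
render_polylines <- function(polys, size, width, bg, fg, supersample = 4L) {
  s <- supersample
  Hs <- size * s
  M <- matrix(FALSE, Hs, Hs)
  half <- width / 2
  for (v in polys) {
    nseg <- nrow(v) - 1L
    i <- 1L
    while (i <= nseg) {
      j <- i
      # chunk consecutive segments while bbox stays modest
      while (j < nseg &&
             max(abs(v[j + 1L, ] - v[i, ])) < 24) j <- j + 1L
      p <- v[i:(j + 1L), , drop = FALSE]
      rlo <- max(1L, floor((min(p[, 1L]) - half - 1) * s))
      rhi <- min(Hs, ceiling((max(p[, 1L]) + half + 1) * s))
      clo <- max(1L, floor((min(p[, 2L]) - half - 1) * s))
      chi <- min(Hs, ceiling((max(p[, 2L]) + half + 1) * s))
      if (rlo <= rhi && clo <= chi) {
        rr <- (rlo:rhi - 0.5) / s + 0.5
        cc <- (clo:chi - 0.5) / s + 0.5
        gr <- matrix(rr, length(rr), length(cc))
        gc <- matrix(cc, length(rr), length(cc), byrow = TRUE)
        dmin <- matrix(Inf, length(rr), length(cc))
        for (q in i:j) {
          a <- v[q, ]; b <- v[q + 1L, ]
          ab <- b - a
          len2 <- sum(ab^2)
          if (len2 < 1e-12) next
          t <- ((gr - a[1L]) * ab[1L] + (gc - a[2L]) * ab[2L]) / len2
          t[t < 0] <- 0; t[t > 1] <- 1
          dx <- gr - (a[1L] + t * ab[1L])
          dy <- gc - (a[2L] + t * ab[2L])
          d2 <- dx * dx + dy * dy
          dmin <- pmin(dmin, d2)
        }
        blk <- M[rlo:rhi, clo:chi]
        M[rlo:rhi, clo:chi] <- blk | (dmin <= half^2)
      }
      i <- j + 1L
    }
  }
  # box-downsample s x s blocks to coverage in [0, 1]
  cov <- block_reduce(M * 1, s) / s^2
  bg + (fg - bg) * cov
}

# sum over k x k blocks (dims must be multiples of k)
block_reduce <- function(m, k) {
  H <- nrow(m); W <- ncol(m)
  m1 <- rowsum(m, rep(seq_len(H / k), each = k))
  t(rowsum(t(m1), rep(seq_len(W / k), each = k)))
}

#' Render a synthetic fibre scene with ground truth
#'
#' @param spec a [scene_spec()].
#' @param scale magnification factor: the scene geometry is generated in the
#'   spec's base coordinates (so the layout is identical for every scale)
#'   and then rendered at `scale` times the base resolution — the same scene
#'   imaged at a different pixel size.
#' @return list with `image` (a [gray_image()]), and `truth`: a list holding
#'   `polylines` (the clipped centrelines, in rendered pixel coordinates),
#'   `orientations_deg`, `total_length_px`, `endpoints`, `branchpoints`
#'   (number of crossings between distinct fibres), `n_pieces`.
#' @export
render_scene <- function(spec, scale = 1) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  n <- spec$image_size_px
  polys <- list(); thetas <- numeric(0)
  margin <- spec$fibre_width_px / 2 + 2
  if (spec$n_fibres > 0) {
    for (i in seq_len(spec$n_fibres)) {
      for (attempt in 1:200) {
        centre <- stats::runif(2, margin, n - margin)
        theta <- if (spec$orientation_mode == "aligned")
          (spec$base_orientation_deg + stats::rnorm(1, 0, spec$jitter_deg)) * pi / 180
        else stats::runif(1, 0, pi)
        len <- if (length(spec$length_px) == 2L)
          stats::runif(1, spec$length_px[1L], spec$length_px[2L])
        else spec$length_px
        v <- fibre_polyline(centre, theta, len, spec$waveform)
        pieces <- clip_polyline(v, margin, n - margin)
        if (!length(pieces)) next
        if (spec$min_separation_px > 0 && length(polys)) {
          prev <- do.call(rbind, polys)
          ok <- TRUE
          for (pc in pieces) {
            sub <- pc[seq(1L, nrow(pc), by = 2L), , drop = FALSE]
            d2 <- outer(prev[, 1L], sub[, 1L], `-`)^2 +
                  outer(prev[, 2L], sub[, 2L], `-`)^2
            if (min(d2) < spec$min_separation_px^2) { ok <- FALSE; break }
          }
          if (!ok) next
        }
        for (pc in pieces) {
          polys[[length(polys) + 1L]] <- pc
          thetas <- c(thetas, theta * 180 / pi)
        }
        break
      }
    }
  }
  if (scale != 1)
    polys <- lapply(polys, function(v) (v - 0.5) * scale + 0.5)
  img <- render_polylines(polys, n * scale, spec$fibre_width_px * scale,
                          spec$background_level, spec$fibre_level)
  if (spec$noise_sd > 0)
    img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
  img <- pmin(pmax(img, 0), 255)
  bp <- if (spec$min_separation_px > 0) 0L else count_crossings(polys)
  list(image = gray_image(img),
       truth = list(polylines = polys,
                    orientations_deg = thetas,
                    total_length_px = sum(vapply(polys, polyline_length,
                                                 numeric(1))),
                    endpoints = 2L * length(polys),
                    branchpoints = bp,
                    n_pieces = length(polys)))
}

#' Sinusoidal grating
#'
#' Perfectly oriented stripe field: the analytic gradient orientation is
#' `orientation_deg` everywhere, making this the unit-coherency oracle input.
#'
#' @param size image side, px.
#' @param period_px stripe period, must be at least 4 px (aliasing).
#' @param orientation_deg stripe normal direction in degrees (0 = intensity
#'   varies along columns).
#' @return a [gray_image()].
#' @export
make_stripes <- function(size, period_px = 16, orientation_deg = 0) {
  if (period_px < 4) stop("period_px < 4 px would alias")
  th <- orientation_deg * pi / 180
  r <- matrix(seq_len(size), size, size)
  c_ <- matrix(seq_len(size), size, size, byrow = TRUE)
  phase <- 2 * pi * (c_ * cos(th) + r * sin(th)) / period_px
  gray_image(127.5 + 127.5 * sin(phase))
}

#' Concentric rings
#'
#' Radially symmetric pattern: every gradient orientation is equally
#' represented (dihedral symmetry), the zero-coherency oracle input.
#'
#' @param size image side, px.
#' @param period_px radial period of the rings.
#' @return a [gray_image()].
#' @export
make_rings <- function(size, period_px = 16) {
  ctr <- (size + 1) / 2
  r <- matrix(seq_len(size), size, size)
  c_ <- matrix(seq_len(size), size, size, byrow = TRUE)
  rad <- sqrt((r - ctr)^2 + (c_ - ctr)^2)
  gray_image(127.5 + 127.5 * sin(2 * pi * rad / period_px))
}

#' Sierpinski carpet mask
#'
#' Depth-`d` carpet on a `3^d` grid; the analytic box-counting dimension is
#' `log(8)/log(3) ~ 1.8928`.
#'
#' @param depth recursion depth (image side is `3^depth`).
#' @return a logical matrix.
#' @export
make_sierpinski <- function(depth) {
  if (depth < 1) stop("depth must be >= 1")
  n <- 3L^depth
  ri <- matrix(0:(n - 1L), n, n)
  ci <- matrix(0:(n - 1L), n, n, byrow = TRUE)
  keep <- matrix(TRUE, n, n)
  for (d in seq_len(depth)) {
    p <- 3L^(d - 1L)
    keep <- keep & !((ri %/% p) %% 3L == 1L & (ci %/% p) %% 3L == 1L)
  }
  keep
}

#' Regular grid mask
#'
#' Grid of 1-px fibre lines with square cells of side `cell_px`; the gap
#' oracle (largest inscribed circle per cell has radius `(cell_px - 1)/2`).
#'
#' @param size image side, px.
#' @param cell_px cell period.
#' @return logical matrix.
#' @export
make_grid <- function(size, cell_px) {
  if (cell_px < 2) stop("cell_px must be >= 2")
  m <- matrix(FALSE, size, size)
  lines <- seq(1L, size, by = cell_px)
  m[lines, ] <- TRUE
  m[, lines] <- TRUE
  m
}

#' All-foreground mask with one circular hole
#'
#' The filled mask minus a disc of radius `hole_radius_px`; the gap-analysis
#' oracle (first inscribed circle recovers the hole). Holes tangent to or
#' truncated by the border are handled (the recoverable radius shrinks).
#'
#' @param size image side, px.
#' @param centre `(row, col)` of the hole centre; default image centre.
#' @param hole_radius_px hole radius, px.
#' @return logical matrix (foreground = matrix, hole = background).
#' @export
make_annulus_gap <- function(size, centre = NULL, hole_radius_px) {
  if (is.null(centre)) centre <- c((size + 1) / 2, (size + 1) / 2)
  r <- matrix(seq_len(size), size, size)
  c_ <- matrix(seq_len(size), size, size, byrow = TRUE)
  (r - centre[1L])^2 + (c_ - centre[2L])^2 > hole_radius_px^2
}

#' Degrade an image
#'
#' Controlled acquisition-quality degradations for robustness studies:
#' Gaussian blur of 2 or 3 px radius, additive Gaussian noise (default s.d.
#' 25 on the 8-bit scale, approximating a standard imaging noise injection),
#' block-average downsampling, or under-exposure (intensity scaling).
#'
#' @param img a [gray_image()].
#' @param mode one of `"blur"`, `"noise"`, `"downsample"`, `"underexpose"`.
#' @param radius blur radius (sigma), px; 0 is the identity.
#' @param noise_sd noise standard deviation on the 8-bit scale.
#' @param factor integer downsampling factor.
#' @param exposure multiplicative intensity factor for under-exposure.
#' @param seed RNG seed for the noise mode.
#' @return a degraded [gray_image()].
#' @export
degrade <- function(img, mode = c("blur", "noise", "downsample", "underexpose"),
                    radius = 2, noise_sd = 25, factor = 2, exposure = 0.25,
                    seed = 1L) {
  mode <- match.arg(mode)
  f <- unclass(img)
  out <- switch(mode,
    blur = {
      if (radius <= 0) f
      else t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(f)),
                                               sigma = radius)))
    },
    noise = {
      set.seed(seed)
      f + stats::rnorm(length(f), 0, noise_sd)
    },
    downsample = {
      H <- nrow(f); W <- ncol(f)
      Hk <- (H %/% factor) * factor; Wk <- (W %/% factor) * factor
      if (Hk / factor < 64 || Wk / factor < 64)
        stop("downsampling below 64 px")
      block_reduce(f[seq_len(Hk), seq_len(Wk)], factor) / factor^2
    },
    underexpose = f * exposure)
  gray_image(pmin(pmax(out, 0), 255), pixel_size_um = pixel_size(img))
}
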