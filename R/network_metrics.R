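#' Count fibre end points
#'
#' Number of fibre termini that are free ends: not coincident (within 1.5 px)
#' with any junction, and not the closure point of a closed loop.
#'
#' @param net a [fibre_network()].
#' @return integer count.
#' @export
count_endpoints <- function(net) {
  if (!length(net$fibres)) return(0L)
  info <- terminus_info(net)
  sum(vapply(info, function(i) {
    if (i$closed) 0L else sum(is.na(i$att))
  }, integer(1)))
}

#' Count branch points
#'
#' Number of distinct junction loci where fibres intersect; a four-way
#' crossing counts once.
#'
#' @param net a [fibre_network()].
#' @return integer count.
#' @export
count_branchpoints <- function(net) nrow(net$junctions)

#' Total fibre length
#'
#' Sum of the polyline lengths of all fibres, in microns when the network
#' carries a pixel size, else in pixels.
#'
#' @param net a [fibre_network()].
#' @return scalar length.
#' @export
total_length <- function(net) {
  L <- sum(vapply(net$fibres, polyline_length, numeric(1)))
  if (!is.null(net$pixel_size_um)) L * net$pixel_size_um else L
}

#' Hyphal growth unit
#'
#' Fibre length per end point, `L / E` — the classical hyphal growth unit of
#' filamentous growth analysis. Its inverse `E / L` is the normalised
#' end-point metric (see [normalise_record()]). The reciprocal convention
#' (end points per unit length) is available with `convention = "per_length"`.
#'
#' @param E number of end points.
#' @param L total fibre length.
#' @param convention `"length_per_end"` (default, `L/E`) or `"per_length"`
#'   (`E/L`).
#' @return scalar, or `NA` when `E == 0` (undefined, e.g. pure loops).
#' @export
hgu <- function(E, L, convention = c("length_per_end", "per_length")) {
  convention <- match.arg(convention)
  if (E <= 0) return(NA_real_)
  if (convention == "length_per_end") L / E else E / L
}

#' Average fibre length
#'
#' `L / (0.5 (E + B))`: total length divided by the estimated number of
#' fibres, assuming one of the fibres involved at a branch begins at the
#' branch point.
#'
#' @param L total fibre length.
#' @param E end-point count.
#' @param B branch-point count.
#' @return scalar, or `NA` when `E + B == 0` (e.g. a closed loop).
#' @export
avg_fibre_length <- function(L, E, B) {
  if (E + B <= 0) return(NA_real_)
  L / (0.5 * (E + B))
}

#' Fibre thickness estimate
#'
#' Matrix area (high-density-matrix fraction times image area) divided by
#' total fibre length: the mean width of the material making up the network.
#'
#' @param hdm_area_px matrix area in pixels (or square microns if `L` is in
#'   microns).
#' @param L total fibre length.
#' @return scalar thickness, or `NA` when `L <= 0`.
#' @export
fibre_thickness <- function(hdm_area_px, L) {
  if (L <= 0) return(NA_real_)
  hdm_area_px / L
}

# resample a polyline at points spaced `w` apart in Euclidean (chord)
# distance: from the current sample point, take the first point further along
# the polyline at straight-line distance exactly w.
resample_chord <- function(v, w) {
  out <- v[1L, , drop = FALSE]
  cur <- v[1L, ]
  i <- 1L
  n <- nrow(v)
  frac <- 0           # position within segment i (0..1)
  repeat {
    hit <- NULL
    while (i < n) {
      a <- v[i, ] + frac * (v[i + 1L, ] - v[i, ])
      b <- v[i + 1L, ]
      # solve |a + t (b - a) - cur| = w for t in (0, 1]
      d <- b - a
      f <- a - cur
      A <- sum(d^2); Bq <- 2 * sum(f * d); Cq <- sum(f^2) - w^2
      disc <- Bq^2 - 4 * A * Cq
      if (A > 1e-12 && disc >= 0) {
        t <- (-Bq + sqrt(disc)) / (2 * A)
        if (t > 1e-12 && t <= 1) {
          hit <- a + t * d
          frac <- frac + t * (1 - frac)
          break
        }
      }
      i <- i + 1L
      frac <- 0
    }
    if (is.null(hit)) break
    out <- rbind(out, hit)
    cur <- hit
  }
  out
}

#' Mean fibre curvature at one window
#'
#' Each fibre polyline is resampled at steps of `window_px` (successive
#' points a straight-line distance `window_px` apart along the fibre); the
#' curvature is the mean absolute turning angle, in degrees, between
#' consecutive chords, pooled over all chord pairs of all fibres. Fibres too
#' short to yield two chords contribute nothing. Small windows sense fine
#' waviness; large windows sense coarse bends.
#'
#' @param net a [fibre_network()].
#' @param window_px chord step, pixels (>= 2).
#' @param per_fibre if `TRUE`, average per fibre first, then across fibres;
#'   default pools all chord pairs (long fibres contribute more pairs).
#' @return mean turning angle in degrees, or `NA` if no fibre is long enough.
#' @export
curvature <- function(net, window_px, per_fibre = FALSE) {
  if (window_px < 2) stop("window_px must be >= 2")
  angles_by_fibre <- lapply(net$fibres, function(v) {
    p <- resample_chord(v, window_px)
    if (nrow(p) < 3L) return(numeric(0))
    d <- diff(p)
    dn <- d / sqrt(rowSums(d^2))
    dots <- rowSums(dn[-nrow(dn), , drop = FALSE] * dn[-1L, , drop = FALSE])
    acos(pmin(pmax(dots, -1), 1)) * 180 / pi
  })
  if (per_fibre) {
    m <- vapply(angles_by_fibre, function(a)
      if (length(a)) mean(a) else NA_real_, numeric(1))
    if (all(is.na(m))) NA_real_ else mean(m, na.rm = TRUE)
  } else {
    a <- unlist(angles_by_fibre)
    if (!length(a)) NA_real_ else mean(a)
  }
}

#' Curvature over a range of windows
#'
#' Evaluates [curvature()] at each window in `seq(window_min, window_max,
#' step)`, so fine and coarse curvature scales are reported side by side.
#'
#' @param net a [fibre_network()].
#' @param window_min,window_max window range, pixels.
#' @param step window increment, pixels.
#' @inheritParams curvature
#' @return named numeric vector, names `w<window>`.
#' @export
curvature_sweep <- function(net, window_min, window_max, step = 10,
                            per_fibre = FALSE) {
  if (window_min > window_max) stop("window_min must not exceed window_max")
  if (step < 1) stop("step must be >= 1")
  ws <- seq(window_min, window_max, by = step)
  stats::setNames(vapply(ws, function(w) curvature(net, w, per_fibre),
                         numeric(1)),
                  paste0("w", ws))
}

#' Assemble the per-image metrics record
#'
#' One row of the summary table: raw counts and lengths from the fibre
#' network, global pattern metrics, and the size-normalised variants from
#' [normalise_record()].
#'
#' @param image_id image identifier (file name).
#' @param net a [fibre_network()].
#' @param hdm HDM fraction in `[0, 1]` (or `NA`).
#' @param alignment coherency in `[0, 1]` (or `NA`).
#' @param fractal_dim,lacunarity pattern metrics (or `NA`).
#' @param curvatures named vector from [curvature_sweep()] (or `NULL`).
#' @param gap_stats record from [gap_statistics()] (or `NULL`).
#' @return a one-row `data.frame`.
#' @export
metrics_record <- function(image_id, net, hdm = NA_real_,
                           alignment = NA_real_, fractal_dim = NA_real_,
                           lacunarity = NA_real_, curvatures = NULL,
                           gap_stats = NULL) {
  E <- count_endpoints(net)
  B <- count_branchpoints(net)
  L <- total_length(net)
  area <- prod(net$image_shape)
  if (!is.null(net$pixel_size_um)) area <- area * net$pixel_size_um^2
  hdm_area <- if (is.na(hdm)) NA_real_ else hdm * area
  rec <- data.frame(image_id = image_id,
                    endpoints = E, branchpoints = B, total_length = L,
                    hgu = hgu(E, L),
                    avg_fibre_length = avg_fibre_length(L, E, B),
                    fibre_thickness = if (is.na(hdm_area)) NA_real_
                                      else fibre_thickness(hdm_area, L),
                    alignment = alignment, hdm = hdm,
                    fractal_dim = fractal_dim, lacunarity = lacunarity,
                    stringsAsFactors = FALSE)
  if (!is.null(curvatures))
    for (nm in names(curvatures))
      rec[[paste0("curvature_", nm)]] <- curvatures[[nm]]
  rec <- normalise_record(rec, area)
  if (!is.null(gap_stats))
    for (nm in names(gap_stats)) rec[[nm]] <- gap_stats[[nm]]
  rec
}

#' Size-normalised metrics
#'
#' Raw end-point and branch-point counts and total length scale with the
#' image size in pixels; their normalised versions do not: end points and
#' branch points per unit fibre length (`E/L`, `B/L`; `E/L` is the inverse
#' of the hyphal growth unit) and fibre length per image area (`L/area`,
#' reported per 1000 px^2 for readable magnitudes).
#'
#' @param rec a one-row metrics `data.frame` with columns `endpoints`,
#'   `branchpoints`, `total_length`.
#' @param image_area_px image area (px^2, or um^2 when calibrated).
#' @return `rec` with columns `norm_endpoints`, `norm_branchpoints`,
#'   `norm_length` added (`NA` when `total_length == 0`).
#' @export
normalise_record <- function(rec, image_area_px) {
  L <- rec$total_length
  if (is.na(L) || L <= 0) {
    rec$norm_endpoints <- NA_real_
    rec$norm_branchpoints <- NA_real_
    rec$norm_length <- NA_real_
  } else {
    rec$norm_endpoints <- rec$endpoints / L
    rec$norm_branchpoints <- rec$branchpoints / L
    rec$norm_length <- 1000 * L / image_area_px
  }
  rec
}
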