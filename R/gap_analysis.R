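#' Maximal inscribed circles in matrix-free space
#'
#' Quantifies gaps in the fibre pattern by iteratively fitting circles of
#' decreasing radius into the background of the mask: (1) the Euclidean
#' distance transform of the free space is computed, with fibres, previously
#' placed circles and (by default) the image border as obstacles; (2) a
#' circle is placed at the global distance maximum with that distance as its
#' radius; (3) the circle joins the obstacle set; repeating while the
#' diameter is at least `min_gap_diameter_px`. Circles are returned in
#' extraction order (non-increasing radius) and are pairwise non-overlapping.
#' Ties at the distance maximum break to the smallest `(row, col)`, so the
#' output is deterministic.
#'
#' @param mask logical matrix, foreground = fibre.
#' @param min_gap_diameter_px smallest gap diameter of interest, px (> 0).
#' @param border_obstacle treat the image border as an obstacle so circles
#'   cannot extend outside the field of view (gaps truncated by the border
#'   are then not overstated). Disable for tiled imagery.
#' @param max_circles safety cap on the number of circles.
#' @return a `data.frame` of class `gap_circles` with columns `circle_id`,
#'   `row`, `col`, `radius_px`, `area_px2`; zero rows for an all-foreground
#'   mask.
#' @export
max_inscribed_circles <- function(mask, min_gap_diameter_px,
                                  border_obstacle = TRUE,
                                  max_circles = 10000L) {
  if (!is.numeric(min_gap_diameter_px) || min_gap_diameter_px <= 0)
    stop("`min_gap_diameter_px` must be positive")
  H <- nrow(mask); W <- ncol(mask)
  free <- !mask
  if (border_obstacle) {
    free[c(1L, H), ] <- FALSE
    free[, c(1L, W)] <- FALSE
  }
  rows <- numeric(0); cols <- numeric(0); radii <- numeric(0)
  while (length(radii) < max_circles) {
    if (!any(free)) break
    dm <- EBImage::distmap(free * 1)
    r <- max(dm)
    if (2 * r < min_gap_diameter_px) break
    hits <- which(dm == r)
    rc <- arrayInd(hits, c(H, W))
    pick <- rc[order(rc[, 1L], rc[, 2L])[1L], ]
    rows <- c(rows, pick[1L]); cols <- c(cols, pick[2L]); radii <- c(radii, r)
    # rasterise the circle into the obstacle set
    rr <- max(1L, floor(pick[1L] - r)):min(H, ceiling(pick[1L] + r))
    cc <- max(1L, floor(pick[2L] - r)):min(W, ceiling(pick[2L] + r))
    d2 <- outer((rr - pick[1L])^2, (cc - pick[2L])^2, `+`)
    blk <- free[rr, cc, drop = FALSE]
    blk[d2 <= r^2] <- FALSE
    free[rr, cc] <- blk
  }
  structure(data.frame(circle_id = seq_along(radii), row = rows, col = cols,
                       radius_px = radii, area_px2 = pi * radii^2),
            class = c("gap_circles", "data.frame"))
}

#' Summary statistics of gap circles
#'
#' Count, mean/median/max gap area and the 5th/95th area percentiles of a
#' set of inscribed circles, invariant to input ordering. An empty set gives
#' a zero count with missing averages.
#'
#' @param circles a `gap_circles` data frame from [max_inscribed_circles()].
#' @return named list: `gap_count`, `mean_gap_area`, `median_gap_area`,
#'   `max_gap_area`, `p5_gap_area`, `p95_gap_area`.
#' @export
gap_statistics <- function(circles) {
  a <- circles$area_px2
  if (!length(a)) {
    return(list(gap_count = 0L, mean_gap_area = NA_real_,
                median_gap_area = NA_real_, max_gap_area = NA_real_,
                p5_gap_area = NA_real_, p95_gap_area = NA_real_))
  }
  qs <- stats::quantile(a, c(0.05, 0.95), names = FALSE)
  list(gap_count = length(a), mean_gap_area = mean(a),
       median_gap_area = stats::median(a), max_gap_area = max(a),
       p5_gap_area = qs[1L], p95_gap_area = qs[2L])
}

#' Write the per-image gap CSV
#'
#' One row per circle: `circle_id, row, col, radius_px, area_px2`.
#'
#' @param circles a `gap_circles` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gap_csv <- function(circles, path) {
  df <- as.data.frame(circles)
  df$radius_px <- signif(df$radius_px, 6)
  df$area_px2 <- signif(df$area_px2, 6)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
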