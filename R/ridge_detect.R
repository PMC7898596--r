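#' Ridge-detection parameters
#'
#' Parameters of the curvilinear ridge detector that extracts fibre
#' centrelines. The user-facing scale parameter is the expected fibre width in
#' pixels; the detector's Gaussian scale is derived from it via
#' [sigma_from_width()]. When a range of widths is given, detection runs at
#' widths `min, min + 5, ...` (the maximum is always included) and the
#' per-width masks are amalgamated by pixel-wise union.
#'
#' Hysteresis thresholds are given as intensity contrasts on the 8-bit scale
#' (the contrast between a fibre and its local background): ridges with
#' contrast at least `contrast_high` seed lines, which extend through ridge
#' points of contrast at least `contrast_low`. Internally these are
#' converted to second-derivative response thresholds through the response
#' model of a bar-shaped line profile of the stated width at the detection
#' scale, so the user-facing parameters stay in image-intensity units.
#'
#' @param line_width_min_px,line_width_max_px fibre width range, pixels.
#' @param contrast_high,contrast_low hysteresis thresholds as intensity
#'   contrasts in `[0, 255]`; defaults 100 and 30, intended for images that
#'   have been contrast-saturated to the full 8-bit range.
#' @param min_branch_px minimum branch length; shorter dangling fibres are
#'   pruned (see [prune_short_branches()]).
#' @param dark_lines logical; fibres dark on light background.
#' @param min_response absolute response floor (intensity units per px^2)
#'   guarding against numerical noise on flat backgrounds.
#' @return an object of class `ridge_params`.
#' @export
ridge_params <- function(line_width_min_px = 5,
                         line_width_max_px = line_width_min_px,
                         contrast_high = 100, contrast_low = 30,
                         min_branch_px = 10, dark_lines = FALSE,
                         min_response = 0.5) {
  if (line_width_min_px <= 0) stop("line widths must be positive")
  if (line_width_min_px > line_width_max_px)
    stop("line_width_min_px must not exceed line_width_max_px")
  if (contrast_low > contrast_high)
    stop("contrast_low must not exceed contrast_high")
  if (min_branch_px < 0) stop("min_branch_px must be non-negative")
  structure(list(line_width_min_px = line_width_min_px,
                 line_width_max_px = line_width_max_px,
                 contrast_high = contrast_high, contrast_low = contrast_low,
                 min_branch_px = min_branch_px, dark_lines = dark_lines,
                 min_response = min_response),
            class = "ridge_params")
}

#' Gaussian scale for a given line width
#'
#' The detector's Gaussian derivative scale for fibres of width `w` px is
#' `sigma = w / (2 sqrt(3)) + 0.5`, the convention of the ridge-detection
#' plugin lineage this implementation follows: `w / (2 sqrt(3))` is the
#' smallest scale at which a bar profile of width `w` has a single ridge
#' maximum at its centre, and the `+ 0.5` margin keeps the response
#' well-conditioned.
#'
#' @param line_width_px positive fibre width in pixels.
#' @return the Gaussian sigma in pixels.
#' @export
sigma_from_width <- function(line_width_px) {
  if (!is.numeric(line_width_px) || any(line_width_px <= 0))
    stop("`line_width_px` must be positive")
  line_width_px / (2 * sqrt(3)) + 0.5
}

# peak second-derivative response, per unit contrast, of a bar-shaped line
# profile of width w smoothed at scale sigma (the idealised fibre model)
bar_response_factor <- function(w, sigma) {
  a <- w / 2
  2 * a * exp(-a^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma^3)
}

# 1-D Gaussian and derivative kernels, truncated at 4 sigma
gauss_kernels <- function(sigma) {
  n <- max(2L, ceiling(4 * sigma))
  x <- (-n):n
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  list(g = g,
       gd = -x / sigma^2 * g,
       gdd = (x^2 - sigma^2) / sigma^4 * g)
}

conv2sep <- function(f, kr, kc) {
  EBImage::filter2(f, outer(kr, kc), boundary = "replicate")
}

#' Construct a fibre network
#'
#' @param fibres list of n x 2 matrices of subpixel `(row, col)` vertices;
#'   consecutive vertices at most ~2 px apart.
#' @param junctions m x 2 matrix of `(row, col)` branch-point locations (or
#'   `NULL`).
#' @param image_shape integer vector `c(height, width)`.
#' @param pixel_size_um optional microns per pixel.
#' @return an object of class `fibre_network`.
#' @export
fibre_network <- function(fibres, junctions = NULL, image_shape,
                          pixel_size_um = NULL) {
  fibres <- lapply(fibres, function(v) {
    v <- as.matrix(v)
    if (ncol(v) != 2L || nrow(v) < 2L)
      stop("each fibre needs >= 2 (row, col) vertices")
    storage.mode(v) <- "double"
    colnames(v) <- c("row", "col")
    v
  })
  if (is.null(junctions)) junctions <- matrix(numeric(0), 0L, 2L)
  junctions <- matrix(as.numeric(junctions), ncol = 2L)
  colnames(junctions) <- c("row", "col")
  structure(list(fibres = fibres, junctions = junctions,
                 image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um),
            class = "fibre_network")
}

#' @export
print.fibre_network <- function(x, ...) {
  cat(sprintf("fibre_network: %d fibres, %d junctions, image %d x %d px\n",
              length(x$fibres), nrow(x$junctions),
              x$image_shape[1L], x$image_shape[2L]))
  invisible(x)
}

polyline_length <- function(v) {
  if (nrow(v) < 2L) return(0)
  sum(sqrt(rowSums(diff(v)^2)))
}

#' Detect fibre centrelines at a single line width
#'
#' Steger-style curvilinear ridge detection. Gaussian derivatives at the scale
#' matched to `width_px` give the image Hessian; pixels where the second
#' directional derivative across the line is strongly negative and the
#' subpixel extremum of the profile falls inside the pixel are ridge
#' candidates, localised to subpixel accuracy by a second-order Taylor step
#' along the principal Hessian eigenvector. Candidate points above the high
#' hysteresis threshold seed lines, which grow through candidates above the
#' low threshold by linking nearest-neighbour ridge points of compatible
#' orientation (less than 45 degrees of turn per step). Junctions are
#' recorded where a growing line meets an existing one, and fibres are split
#' there so each fibre is internally junction-free.
#'
#' @param img a [gray_image()] in canonical polarity (fibres bright).
#' @param params a [ridge_params()] object.
#' @param width_px the line width for this pass; defaults to
#'   `params$line_width_min_px`.
#' @return a [fibre_network()].
#' @export
detect_lines <- function(img, params = ridge_params(), width_px = NULL) {
  if (is.null(width_px)) width_px <- params$line_width_min_px
  f <- unclass(img)
  H <- nrow(f); W <- ncol(f)
  if (width_px < 1 || width_px > min(H, W) / 4)
    stop("width_px must lie in [1, min(image dims)/4]")
  sigma <- sigma_from_width(width_px)
  if (min(H, W) < 4 * sigma)
    stop("image smaller than 4 sigma in one dimension")
  k <- gauss_kernels(sigma)

  gr  <- conv2sep(f, k$gd,  k$g)    # d/drow
  gc  <- conv2sep(f, k$g,   k$gd)   # d/dcol
  frr <- conv2sep(f, k$gdd, k$g)
  fcc <- conv2sep(f, k$g,   k$gdd)
  frc <- conv2sep(f, k$gd,  k$gd)

  tr   <- frr + fcc
  disc <- sqrt((frr - fcc)^2 + 4 * frc^2)
  l2   <- (tr - disc) / 2           # most negative eigenvalue (across line)
  l1   <- (tr + disc) / 2           # along-line eigenvalue, ~0 on true lines

  # eigenvector of l2, taking the better-conditioned of the two formulations
  v1r <- frc;       v1c <- l2 - frr
  v2r <- l2 - fcc;  v2c <- frc
  use1 <- (v1r^2 + v1c^2) >= (v2r^2 + v2c^2)
  nr <- v1r; nr[!use1] <- v2r[!use1]
  nc <- v1c; nc[!use1] <- v2c[!use1]
  nn <- sqrt(nr^2 + nc^2)
  defined <- l2 < 0 & nn > 1e-12
  nn[nn < 1e-300] <- 1
  nr <- nr / nn; nc <- nc / nn

  denom <- l2
  denom[!defined] <- -1
  tt <- -(gr * nr + gc * nc) / denom
  offr <- tt * nr
  offc <- tt * nc
  # line-quality gates: blobs and saddles (line end caps, crossing plateaus)
  # have an along-line eigenvalue comparable to the cross-line one, true
  # line interiors do not. Points failing the lenient ratio are never part
  # of a line; seeding demands a clean line point.
  # the 0.6 acceptance window (rather than the pixel half-width 0.5) keeps
  # lines running midway between two pixel rows, where the interpolated
  # extremum can land just outside both pixels
  cand <- defined & abs(offr) <= 0.6 & abs(offc) <= 0.6 &
    abs(l1) <= 0.8 * abs(l2)
  clean <- cand & abs(l1) <= 0.3 * abs(l2)
  resp <- matrix(0, H, W)
  resp[cand] <- -l2[cand]

  # convert intensity-contrast thresholds to second-derivative response
  # scale via the bar-profile response model at this width and sigma
  fac <- bar_response_factor(width_px, sigma)
  hi <- max(params$contrast_high * fac, 2 * params$min_response)
  lo <- max(params$contrast_low * fac, params$min_response)
  lo <- min(lo, hi)

  link_ridge_points(resp, cand, clean, offr, offc, nr, nc, hi, lo,
                    width_px = width_px, image_shape = c(H, W),
                    pixel_size_um = pixel_size(img))
}

# hysteresis linking of ridge candidates into fibre polylines
link_ridge_points <- function(resp, cand, clean, offr, offc, nr, nc, hi, lo,
                              width_px, image_shape, pixel_size_um = NULL) {
  H <- image_shape[1L]; W <- image_shape[2L]
  # line tangent = eigenvector rotated 90 degrees
  tr_ <- -nc; tc_ <- nr
  pr <- .row(c(H, W)) + offr   # subpixel positions
  pc <- .col(c(H, W)) + offc

  usable <- cand & resp >= lo
  seeds <- which(clean & resp >= hi)
  seeds <- seeds[order(resp[seeds], decreasing = TRUE)]
  status <- integer(H * W)

  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1,  0,  1, -1, 1, -1, 0, 1))
  offs_unit <- offs / sqrt(rowSums(offs^2))
  look_ahead <- max(2L, as.integer(ceiling(width_px / 2)) + 1L)
  cos45 <- cos(pi / 4)

  fibre_paths <- list()
  jn_events <- list()   # list(idx = pixel index, fid = fibre hit)
  nfib <- 0L

  # a staircase step can leave two adjacent pixels holding the same subpixel
  # ridge point; once one is traced, retire its twin so it cannot seed a
  # duplicate line
  consume_dups <- function(idx) {
    r0 <- (idx - 1L) %% H + 1L
    c0 <- (idx - 1L) %/% H + 1L
    for (j in 1:8) {
      r1 <- r0 + offs[j, 1L]; c1 <- c0 + offs[j, 2L]
      if (r1 < 1L || r1 > H || c1 < 1L || c1 > W) next
      idx2 <- (c1 - 1L) * H + r1
      if (status[idx2] != 0L || !cand[idx2]) next
      if ((pr[idx2] - pr[idx])^2 + (pc[idx2] - pc[idx])^2 < 0.75^2)
        status[idx2] <<- -1L
    }
  }

  walk <- function(start, d, fid) {
    cur <- start
    out <- integer(0)
    term <- NULL
    repeat {
      r0 <- (cur - 1L) %% H + 1L
      c0 <- (cur - 1L) %/% H + 1L
      dots <- offs_unit[, 1L] * d[1L] + offs_unit[, 2L] * d[2L]
      cand_off <- which(dots >= 0.38)
      best <- 0L; best_score <- Inf; best_key <- c(Inf, Inf, Inf)
      hit_used <- 0L; hit_dist <- Inf
      for (j in cand_off) {
        r1 <- r0 + offs[j, 1L]; c1 <- c0 + offs[j, 2L]
        if (r1 < 1L || r1 > H || c1 < 1L || c1 > W) next
        idx2 <- (c1 - 1L) * H + r1
        if (!usable[idx2]) next
        ct <- abs(tr_[idx2] * d[1L] + tc_[idx2] * d[2L])
        if (ct < cos45) next
        st <- status[idx2]
        if (st == fid || st == -1L) next
        dd <- sqrt((pr[idx2] - pr[cur])^2 + (pc[idx2] - pc[cur])^2)
        if (st > 0L) {
          if (dd < hit_dist) { hit_used <- idx2; hit_dist <- dd }
          next
        }
        adiff <- acos(min(ct, 1))
        score <- dd + adiff
        key <- c(score, adiff, (r1 - 1) * W + c1)   # spec tie-break order
        if (key[1L] < best_key[1L] - 1e-12 ||
            (abs(key[1L] - best_key[1L]) <= 1e-12 &&
             (key[2L] < best_key[2L] - 1e-12 ||
              (abs(key[2L] - best_key[2L]) <= 1e-12 && key[3L] < best_key[3L])))) {
          best <- idx2; best_key <- key; best_score <- score
        }
      }
      if (best > 0L) {
        status[best] <<- fid
        consume_dups(best)
        out <- c(out, best)
        t2 <- c(tr_[best], tc_[best])
        if (t2[1L] * d[1L] + t2[2L] * d[2L] < 0) t2 <- -t2
        d <- t2
        cur <- best
        next
      }
      if (hit_used > 0L) {
        term <- hit_used
        break
      }
      # look ahead across a possible crossing plateau for an existing line
      perp <- c(-d[2L], d[1L])
      found <- 0L
      for (kk in seq_len(look_ahead)) {
        base_r <- pr[cur] + kk * d[1L]; base_c <- pc[cur] + kk * d[2L]
        for (side in c(0, -1, 1)) {
          r1 <- as.integer(round(base_r + side * perp[1L]))
          c1 <- as.integer(round(base_c + side * perp[2L]))
          if (r1 < 1L || r1 > H || c1 < 1L || c1 > W) next
          idx2 <- (c1 - 1L) * H + r1
          st <- status[idx2]
          if (st > 0L && st != fid) { found <- idx2; break }
        }
        if (found > 0L) break
      }
      if (found > 0L) term <- found
      break
    }
    list(path = out, term = term)
  }

  for (s in seeds) {
    if (status[s] != 0L) next
    nfib <- nfib + 1L
    fid <- nfib
    status[s] <- fid
    consume_dups(s)
    d0 <- c(tr_[s], tc_[s])
    w1 <- walk(s, d0, fid)
    w2 <- walk(s, -d0, fid)
    idxs <- c(rev(w2$path), s, w1$path)
    verts <- cbind(pr[idxs], pc[idxs])
    # terminal junction attachments: append the met line's point as terminus
    if (!is.null(w2$term)) {
      verts <- rbind(c(pr[w2$term], pc[w2$term]), verts)
      jn_events[[length(jn_events) + 1L]] <-
        list(at = c(pr[w2$term], pc[w2$term]), pix = w2$term,
             fid = status[w2$term], src = fid)
    }
    if (!is.null(w1$term)) {
      verts <- rbind(verts, c(pr[w1$term], pc[w1$term]))
      jn_events[[length(jn_events) + 1L]] <-
        list(at = c(pr[w1$term], pc[w1$term]), pix = w1$term,
             fid = status[w1$term], src = fid)
    }
    if (nrow(verts) >= 2L) {
      attr(verts, "traced") <- idxs
      fibre_paths[[fid]] <- verts
    } else {
      fibre_paths[[fid]] <- NULL
      status[s] <- -1L   # isolated single point: consumed, no fibre
      nfib <- nfib - 1L
    }
  }

  split_at_junctions(fibre_paths, jn_events, c(H, W), pixel_size_um)
}

# split fibres where other lines attached to them; deduplicate junction loci
split_at_junctions <- function(fibre_paths, jn_events, image_shape,
                               pixel_size_um) {
  jpts <- matrix(numeric(0), 0L, 2L)
  if (length(jn_events)) {
    # a contact in the interior of another fibre is a branch (a T or a
    # crossing traced through); a contact at another fibre's terminus is a
    # branch only where three or more fibre ends meet — with two fibres it
    # is a continuation the tracer broke, to be re-merged, not a junction
    interior <- vapply(jn_events, function(e) {
      v <- fibre_paths[[e$fid]]
      if (is.null(v)) return(FALSE)
      idxs <- attr(v, "traced")
      k <- match(e$pix, idxs)
      # a margin below the look-ahead reach, so hits just inside a terminus
      # still count as end contacts
      !is.na(k) && k > 5L && k < length(idxs) - 4L
    }, logical(1))
    jpts <- do.call(rbind, lapply(jn_events[interior], function(e) e$at))
    if (is.null(jpts)) jpts <- matrix(numeric(0), 0L, 2L)
    ends <- jn_events[!interior]
    if (length(ends)) {
      epos <- do.call(rbind, lapply(ends, function(e) e$at))
      assigned <- rep(0L, length(ends))
      ncl <- 0L
      reps <- matrix(numeric(0), 0L, 2L)
      for (i in seq_along(ends)) {
        if (ncl > 0L) {
          d2 <- (reps[, 1L] - epos[i, 1L])^2 + (reps[, 2L] - epos[i, 2L])^2
          h <- which(d2 <= 2.5^2)
          if (length(h)) { assigned[i] <- h[1L]; next }
        }
        ncl <- ncl + 1L
        reps <- rbind(reps, epos[i, ])
        assigned[i] <- ncl
      }
      substantial <- function(f) {
        v <- fibre_paths[[f]]
        !is.null(v) && length(attr(v, "traced")) >= 5L
      }
      for (cl in seq_len(ncl)) {
        members <- ends[assigned == cl]
        fids <- unique(unlist(lapply(members, function(e) c(e$fid, e$src))))
        fids <- fids[vapply(fids, substantial, logical(1))]
        if (length(fids) >= 3L)
          jpts <- rbind(jpts, reps[cl, ])
      }
    }
  }
  keep <- !vapply(fibre_paths, is.null, logical(1))
  fibre_paths <- fibre_paths[keep]
  # cluster junction loci closer than 1.5 px into single branch points
  jpos <- dedupe_points(jpts, 1.5)
  if (nrow(jpos)) {
    out <- list()
    for (v in fibre_paths) {
      n <- nrow(v)
      cuts <- integer(0)
      for (q in seq_len(nrow(jpos))) {
        d2 <- (v[, 1L] - jpos[q, 1L])^2 + (v[, 2L] - jpos[q, 2L])^2
        kmin <- which.min(d2)
        if (d2[kmin] <= 1.5^2 && kmin > 1L && kmin < n)
          cuts <- c(cuts, kmin)
      }
      cuts <- sort(unique(cuts))
      bounds <- c(1L, cuts, n)
      for (b in seq_len(length(bounds) - 1L)) {
        seg <- v[bounds[b]:bounds[b + 1L], , drop = FALSE]
        if (nrow(seg) >= 2L && polyline_length(seg) > 0)
          out[[length(out) + 1L]] <- seg
      }
    }
    fibre_paths <- out
  }
  fibre_paths <- Filter(function(v) nrow(v) >= 2L && polyline_length(v) > 0,
                        fibre_paths)
  fibre_paths <- merge_collinear_ends(fibre_paths, jpos)
  fibre_network(fibre_paths, jpos, image_shape, pixel_size_um)
}

# rejoin fibres the tracer broke: termini of distinct fibres that nearly
# touch, point along each other, and are away from any junction locus
merge_collinear_ends <- function(fibres, jpos, max_gap = 3, max_angle = 50) {
  cosmax <- cos(max_angle * pi / 180)
  end_dir <- function(v, which_end) {
    n <- nrow(v)
    d <- if (which_end == 1L) v[1L, ] - v[min(3L, n), ]
         else v[n, ] - v[max(1L, n - 2L), ]
    d / max(sqrt(sum(d^2)), 1e-12)
  }
  near_junction <- function(p) {
    nrow(jpos) > 0L &&
      min((jpos[, 1L] - p[1L])^2 + (jpos[, 2L] - p[2L])^2) <= 2.5^2
  }
  repeat {
    merged <- FALSE
    nf <- length(fibres)
    if (nf < 2L) break
    for (a in seq_len(nf - 1L)) {
      va <- fibres[[a]]
      for (ea in 1:2) {
        pa <- if (ea == 1L) va[1L, ] else va[nrow(va), ]
        if (near_junction(pa)) next
        da <- end_dir(va, ea)
        for (b in (a + 1L):nf) {
          vb <- fibres[[b]]
          for (eb in 1:2) {
            pb <- if (eb == 1L) vb[1L, ] else vb[nrow(vb), ]
            if (sum((pa - pb)^2) > max_gap^2 || near_junction(pb)) next
            db <- end_dir(vb, eb)
            # ends must point towards each other (opposed directions)
            if (sum(da * -db) < cosmax) next
            # staircase twins can make broken pieces overlap by ~a pixel;
            # only enforce the gap direction for genuine gaps
            gap <- pb - pa
            gl <- sqrt(sum(gap^2))
            if (gl > 1.5 && sum(da * gap) / gl < cos(70 * pi / 180)) next
            A <- if (ea == 1L) va[rev(seq_len(nrow(va))), , drop = FALSE] else va
            Bm <- if (eb == 1L) vb else vb[rev(seq_len(nrow(vb))), , drop = FALSE]
            fibres[[a]] <- rbind(A, Bm)
            fibres <- fibres[-b]
            merged <- TRUE
            break
          }
          if (merged) break
        }
        if (merged) break
      }
      if (merged) break
    }
    if (!merged) break
  }
  fibres
}

dedupe_points <- function(pts, tol) {
  if (nrow(pts) <= 1L) return(pts)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts) - 1L)) {
    if (!keep[i]) next
    later <- (i + 1L):nrow(pts)
    d2 <- (pts[later, 1L] - pts[i, 1L])^2 + (pts[later, 2L] - pts[i, 2L])^2
    keep[later[d2 <= tol^2]] <- FALSE
  }
  pts[keep, , drop = FALSE]
}

# fibre termini and their junction attachment (within 1.5 px)
terminus_info <- function(net) {
  J <- net$junctions
  lapply(net$fibres, function(v) {
    ends <- rbind(v[1L, ], v[nrow(v), ])
    att <- c(NA_integer_, NA_integer_)
    if (nrow(J)) {
      for (e in 1:2) {
        d2 <- (J[, 1L] - ends[e, 1L])^2 + (J[, 2L] - ends[e, 2L])^2
        k <- which.min(d2)
        if (d2[k] <= 1.5^2) att[e] <- k
      }
    }
    list(ends = ends, att = att,
         closed = nrow(v) > 2L && sqrt(sum((v[1L, ] - v[nrow(v), ])^2)) <= 1.5)
  })
}

#' Prune short dangling branches
#'
#' Removes every fibre that terminates in a free end point (not a junction)
#' and is shorter than `min_branch_px`, then dissolves junctions left with
#' fewer than three attached fibres (two remaining fibres are merged into a
#' single through-fibre), repeating until stable. This suppresses the
#' erroneous identification of very small filaments.
#'
#' @param net a [fibre_network()].
#' @param min_branch_px minimum branch length in pixels; `0` is the identity.
#' @return the pruned [fibre_network()].
#' @export
prune_short_branches <- function(net, min_branch_px) {
  if (min_branch_px <= 0) return(net)
  repeat {
    if (!length(net$fibres)) break
    info <- terminus_info(net)
    lens <- vapply(net$fibres, polyline_length, numeric(1))
    has_free <- vapply(info, function(i) !i$closed && anyNA(i$att), logical(1))
    closed <- vapply(info, function(i) i$closed, logical(1))
    # degenerate micro-loops (tracer artefacts at fibre ends) go with the
    # free-ended twigs
    drop <- (has_free | closed) & lens < min_branch_px
    if (any(drop)) {
      net <- fibre_network(net$fibres[!drop], net$junctions,
                           net$image_shape, net$pixel_size_um)
      next
    }
    # dissolve the first junction left with fewer than three attachments;
    # two remaining attached fibres merge into a single through-fibre
    J <- net$junctions
    if (!nrow(J)) break
    att_count <- integer(nrow(J))
    for (i in seq_along(info))
      for (e in 1:2)
        if (!is.na(info[[i]]$att[e]))
          att_count[info[[i]]$att[e]] <- att_count[info[[i]]$att[e]] + 1L
    q <- which(att_count < 3L)[1L]
    if (is.na(q)) break
    fibres <- net$fibres
    members <- which(vapply(info, function(i) q %in% i$att, logical(1)))
    if (length(members) == 2L) {
      a <- members[1L]; b <- members[2L]
      va <- fibres[[a]]; vb <- fibres[[b]]
      # orient so a ends at the junction and b starts there
      if (!is.na(info[[a]]$att[1L]) && info[[a]]$att[1L] == q)
        va <- va[rev(seq_len(nrow(va))), , drop = FALSE]
      if (is.na(info[[b]]$att[1L]) || info[[b]]$att[1L] != q)
        vb <- vb[rev(seq_len(nrow(vb))), , drop = FALSE]
      fibres[[a]] <- rbind(va, vb)
      fibres <- fibres[-b]
    }
    net <- fibre_network(fibres, J[-q, , drop = FALSE],
                         net$image_shape, net$pixel_size_um)
  }
  net
}

bresenham_seg <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  n <- max(dr, dc) + 1L
  cbind(as.integer(round(seq(r0, r1, length.out = n))),
        as.integer(round(seq(c0, c1, length.out = n))))
}

#' Rasterise a fibre network into a binary mask
#'
#' Traces each fibre polyline as a one-pixel-wide 8-connected foreground path
#' (Bresenham-style between consecutive vertices).
#'
#' @param net a [fibre_network()].
#' @return a logical matrix of the network's `image_shape`.
#' @export
rasterize <- function(net) {
  H <- net$image_shape[1L]; W <- net$image_shape[2L]
  mask <- matrix(FALSE, H, W)
  for (v in net$fibres) {
    rv <- round(v[, 1L]); cv <- round(v[, 2L])
    for (i in seq_len(nrow(v) - 1L)) {
      px <- bresenham_seg(rv[i], cv[i], rv[i + 1L], cv[i + 1L])
      px[, 1L] <- pmin(pmax(px[, 1L], 1L), H)
      px[, 2L] <- pmin(pmax(px[, 2L], 1L), W)
      mask[px] <- TRUE
    }
  }
  mask
}

#' Multi-width detection with mask amalgamation
#'
#' Runs [detect_lines()] at line widths `min, min + 5, min + 10, ...` up to
#' the maximum (which is always included even if off the 5-px grid), prunes
#' each network, and amalgamates the per-width rasterised masks by pixel-wise
#' union. If `min == max` a single width is evaluated.
#'
#' @param img a [gray_image()] in canonical polarity.
#' @param params a [ridge_params()].
#' @return list with `mask` (amalgamated logical matrix), `networks` (named
#'   list of pruned [fibre_network()]s, one per width), and `masks` (named
#'   list of per-width masks).
#' @export
detect_multiscale <- function(img, params = ridge_params()) {
  widths <- seq(params$line_width_min_px, params$line_width_max_px, by = 5)
  if (widths[length(widths)] != params$line_width_max_px)
    widths <- c(widths, params$line_width_max_px)
  networks <- list(); masks <- list()
  for (w in widths) {
    net <- detect_lines(img, params, width_px = w)
    net <- prune_short_branches(net, params$min_branch_px)
    key <- as.character(w)
    networks[[key]] <- net
    masks[[key]] <- rasterize(net)
  }
  amalgam <- Reduce(`|`, masks)
  list(mask = amalgam, networks = networks, masks = masks)
}
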