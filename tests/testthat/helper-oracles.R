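# shared test helpers: geometry oracles and toy-network builders

# min distance from each (row, col) point to a polyline's segments
seg_dist <- function(pts, poly) {
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(poly) - 1L)) {
    a <- poly[i, ]; b <- poly[i + 1L, ]
    ab <- b - a
    l2 <- sum(ab^2)
    if (l2 < 1e-12) next
    t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L]) / l2
    t <- pmin(pmax(t, 0), 1)
    dmin <- pmin(dmin, sqrt((pts[, 1L] - a[1L] - t * ab[1L])^2 +
                            (pts[, 2L] - a[2L] - t * ab[2L])^2))
  }
  dmin
}

# coverage of the true centrelines by a detected network, and the RMSE of
# the detected centreline against the truth where covered
centreline_recovery <- function(truth_polys, net, tol = 1.5) {
  tsamp <- do.call(rbind, lapply(truth_polys, function(v)
    fibremetrics:::resample_chord(v, 1)))
  dmin <- rep(Inf, nrow(tsamp))
  for (V in net$fibres) dmin <- pmin(dmin, seg_dist(tsamp, V))
  list(coverage = mean(dmin <= tol),
       rmse = sqrt(mean(dmin[dmin <= tol]^2)))
}

# polyline between two points sampled at ~1.5 px steps
poly_between <- function(a, b) {
  n <- max(2L, ceiling(sqrt(sum((b - a)^2)) / 1.5) + 1L)
  cbind(seq(a[1L], b[1L], length.out = n), seq(a[2L], b[2L], length.out = n))
}

# Y-shaped network: three arms meeting at a junction
make_y_network <- function(shape = c(100L, 100L)) {
  j <- c(50, 50)
  arms <- list(c(10, 50), c(80, 20), c(80, 80))
  fibre_network(lapply(arms, function(a) poly_between(a, j)),
                junctions = matrix(j, 1L), image_shape = shape)
}

# closed loop (circle polyline, first vertex repeated at the end)
make_loop_network <- function(shape = c(100L, 100L), r = 30) {
  phi <- seq(0, 2 * pi, length.out = 150L)
  v <- cbind(50 + r * cos(phi), 50 + r * sin(phi))
  fibre_network(list(v), NULL, shape)
}

# random embedded tree with a degree oracle: nodes >= 8 px apart, fibres are
# maximal paths between nodes of degree != 2 (degree-2 nodes are interior
# polyline vertices, junctions = degree >= 3 nodes)
random_toy_network <- function(seed, shape = c(400L, 400L)) {
  set.seed(seed)
  n_nodes <- sample(6:12, 1L)
  repeat {
    pos <- cbind(runif(n_nodes, 20, shape[1L] - 20),
                 runif(n_nodes, 20, shape[2L] - 20))
    ok <- TRUE
    for (i in seq_len(n_nodes - 1L)) {
      d2 <- (pos[-(1:i), 1L, drop = FALSE] - pos[i, 1L])^2 +
            (pos[-(1:i), 2L, drop = FALSE] - pos[i, 2L])^2
      if (min(d2) < 8^2) { ok <- FALSE; break }
    }
    if (ok) break
  }
  parent <- c(NA, vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L),
                         integer(1)))
  edges <- cbind(2:n_nodes, parent[-1L])
  deg <- tabulate(c(edges), nbins = n_nodes)
  adj <- lapply(seq_len(n_nodes), function(i)
    setdiff(unique(c(edges[edges[, 1L] == i, 2L],
                     edges[edges[, 2L] == i, 1L])), i))
  used <- matrix(FALSE, n_nodes, n_nodes)
  fibres <- list()
  terminals <- which(deg != 2L)
  for (t0 in terminals) {
    for (nb in adj[[t0]]) {
      if (used[t0, nb]) next
      path <- c(t0, nb)
      used[t0, nb] <- used[nb, t0] <- TRUE
      while (deg[path[length(path)]] == 2L) {
        cur <- path[length(path)]
        nxt <- setdiff(adj[[cur]], path[length(path) - 1L])
        used[cur, nxt] <- used[nxt, cur] <- TRUE
        path <- c(path, nxt)
      }
      v <- do.call(rbind, lapply(seq_len(length(path) - 1L), function(k)
        poly_between(pos[path[k], ], pos[path[k + 1L], ])[-1L, , drop = FALSE]))
      fibres[[length(fibres) + 1L]] <- rbind(pos[path[1L], ], v)
    }
  }
  jn <- pos[deg >= 3L, , drop = FALSE]
  list(net = fibre_network(fibres, jn, shape),
       edges = edges, pos = pos, deg = deg)
}

# small scene bundle used by several detection tests
detect_scene <- function(w, seed, mode = "isotropic", size = 256L,
                         n_fibres = 8L) {
  sc <- render_scene(scene_spec(size, n_fibres = n_fibres,
                                orientation_mode = mode, jitter_deg = 5,
                                fibre_width_px = w,
                                min_separation_px = 2 * w + 6,
                                length_px = c(70, 150), seed = seed))
  net <- prune_short_branches(detect_lines(sc$image, ridge_params(w)),
                              max(10, 2 * w))
  list(scene = sc, net = net)
}
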