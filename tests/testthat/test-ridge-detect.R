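test_that("sigma follows the line-width convention and rejects bad widths", {
  expect_equal(sigma_from_width(4), 4 / (2 * sqrt(3)) + 0.5, tolerance = 1e-12)
  w <- seq(1, 20, by = 0.5)
  expect_true(all(diff(sigma_from_width(w)) > 0))
  expect_error(sigma_from_width(0), "positive")
})

test_that("a single straight line is recovered as one subpixel-accurate fibre", {
  v <- cbind(rep(64.3, 100), seq(15, 114, length.out = 100))
  img <- gray_image(fibremetrics:::render_polylines(list(v), 128, 4, 10, 200))
  net <- prune_short_branches(detect_lines(img, ridge_params(4)), 10)
  expect_length(net$fibres, 1L)
  expect_equal(count_endpoints(net), 2L)
  expect_equal(count_branchpoints(net), 0L)
  V <- net$fibres[[1L]]
  mid <- V[V[, 2L] > 20 & V[, 2L] < 110, , drop = FALSE]
  expect_lt(max(abs(mid[, 1L] - 64.3)), 0.5)
  expect_gt(total_length(net), 0.95 * 99)
})

test_that("a blank image yields an empty network and zeroed metrics", {
  img <- gray_image(matrix(10, 128, 128))
  net <- detect_lines(img, ridge_params(4))
  expect_length(net$fibres, 0L)
  expect_equal(count_endpoints(net), 0L)
  expect_equal(total_length(net), 0)
  expect_false(any(rasterize(net)))
})

test_that("a '+' cross yields one junction near the true crossing", {
  v1 <- cbind(rep(64.2, 100), seq(15, 114, length.out = 100))
  v2 <- cbind(seq(15, 114, length.out = 100), rep(63.8, 100))
  img <- gray_image(fibremetrics:::render_polylines(list(v1, v2), 128, 4, 10, 200))
  net <- prune_short_branches(detect_lines(img, ridge_params(4)), 10)
  expect_gte(count_branchpoints(net), 1L)
  d <- sqrt((net$junctions[, 1L] - 64.2)^2 + (net$junctions[, 2L] - 63.8)^2)
  expect_lt(min(d), 2)
  expect_equal(count_endpoints(net), 4L)
})

test_that("detect_lines rejects out-of-range widths", {
  img <- gray_image(matrix(10, 64, 64))
  expect_error(detect_lines(img, ridge_params(4), width_px = 40), "width_px")
  expect_error(detect_lines(img, ridge_params(4), width_px = 0.5), "width_px")
})

test_that("pruning removes short twigs and dissolves their junctions", {
  # through-line with a 3 px twig hanging off a junction
  j <- c(50, 50)
  f1 <- poly_between(c(50, 10), j)
  f2 <- poly_between(j, c(50, 90))
  twig <- poly_between(j, c(53, 50))
  net <- fibre_network(list(f1, f2, twig), matrix(j, 1L), c(100L, 100L))
  pr <- prune_short_branches(net, 10)
  expect_length(pr$fibres, 1L)              # merged into one through-fibre
  expect_equal(count_branchpoints(pr), 0L)
  expect_equal(count_endpoints(pr), 2L)
  expect_equal(total_length(pr), 80, tolerance = 1)
  # min 0 is the identity; a long fibre is untouched
  expect_identical(prune_short_branches(net, 0), net)
  solo <- fibre_network(list(poly_between(c(10, 10), c(90, 90))), NULL,
                        c(100L, 100L))
  expect_length(prune_short_branches(solo, 10)$fibres, 1L)
})

test_that("rasterisation traces exact pixels and respects the length bound", {
  f <- fibre_network(list(cbind(c(10, 10), c(5, 50))), NULL, c(60L, 60L))
  m <- rasterize(f)
  expect_equal(sum(m), 46L)
  expect_true(all(m[10, 5:50]))
  expect_false(any(m[-10, ]))
  set.seed(4)
  sc <- render_scene(scene_spec(128, n_fibres = 5, fibre_width_px = 3,
                                orientation_mode = "isotropic",
                                min_separation_px = 10,
                                length_px = c(40, 80), seed = 4))
  net <- prune_short_branches(detect_lines(sc$image, ridge_params(3)), 10)
  m2 <- rasterize(net)
  nvert <- sum(vapply(net$fibres, nrow, integer(1)))
  expect_lte(sum(m2), ceiling(total_length(net)) + nvert)
})

test_that("multi-width sweep uses 5 px increments and unions the masks", {
  v1 <- cbind(seq(40, 200, length.out = 120), rep(60, 120))
  v2 <- cbind(seq(40, 200, length.out = 120), rep(160, 120))
  thin <- fibremetrics:::render_polylines(list(v1), 256, 3, 10, 200)
  thick <- fibremetrics:::render_polylines(list(v2), 256, 15, 10, 200)
  img <- gray_image(pmax(thin, thick))

  one <- detect_multiscale(img, ridge_params(4, 4))
  expect_named(one$networks, "4")
  expect_identical(one$mask, one$masks[["4"]])

  sweep <- detect_multiscale(img, ridge_params(5, 20, min_branch_px = 10))
  expect_named(sweep$networks, c("5", "10", "15", "20"))
  for (m in sweep$masks) expect_true(all(sweep$mask[m]))

  both <- detect_multiscale(img, ridge_params(3, 15, min_branch_px = 10))
  # thin line caught at small width; both present in the amalgam
  small_cols <- vapply(both$networks[["3"]]$fibres,
                       function(v) mean(v[, 2L]), numeric(1))
  expect_true(any(abs(small_cols - 60) < 3))
  expect_true(any(both$mask[, 58:62]))
  expect_true(any(both$mask[, 158:162]))
})

test_that("detection is equivariant under integer translation and 90-degree rotation", {
  sc <- render_scene(scene_spec(200, n_fibres = 6, fibre_width_px = 4,
                                orientation_mode = "isotropic",
                                min_separation_px = 14,
                                length_px = c(60, 120), seed = 3))
  img <- unclass(sc$image)
  net1 <- prune_short_branches(detect_lines(gray_image(img), ridge_params(4)), 10)

  rot <- t(img)[ncol(img):1, ]
  net2 <- prune_short_branches(detect_lines(gray_image(rot), ridge_params(4)), 10)
  expect_equal(length(net2$fibres), length(net1$fibres))
  expect_equal(total_length(net2), total_length(net1), tolerance = 0.01)

  # shift by (+7, +5); fibres sit away from borders by construction
  sh <- matrix(10, 200, 200)
  sh[8:200, 6:200] <- img[1:193, 1:195]
  net3 <- prune_short_branches(detect_lines(gray_image(sh), ridge_params(4)), 10)
  expect_equal(length(net3$fibres), length(net1$fibres))
  mids1 <- sort(vapply(net1$fibres, function(v) v[round(nrow(v) / 2), 1L] +
                         v[round(nrow(v) / 2), 2L], numeric(1)))
  mids3 <- sort(vapply(net3$fibres, function(v) v[round(nrow(v) / 2), 1L] +
                         v[round(nrow(v) / 2), 2L], numeric(1)))
  expect_equal(mids3, mids1 + 12, tolerance = 1.5)
})
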