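test_that("end points and branch points follow network topology", {
  line <- fibre_network(list(poly_between(c(10, 10), c(10, 90))), NULL,
                        c(100L, 100L))
  expect_equal(count_endpoints(line), 2L)
  expect_equal(count_branchpoints(line), 0L)

  expect_equal(count_endpoints(make_loop_network()), 0L)
  expect_equal(count_branchpoints(make_loop_network()), 0L)

  y <- make_y_network()
  expect_equal(count_endpoints(y), 3L)
  expect_equal(count_branchpoints(y), 1L)

  two <- fibre_network(list(poly_between(c(10, 10), c(10, 90)),
                            poly_between(c(50, 10), c(50, 90))), NULL,
                       c(100L, 100L))
  expect_equal(count_endpoints(two), 4L)
  expect_equal(count_branchpoints(two), 0L)
})

test_that("total length sums polyline lengths, in microns when calibrated", {
  h <- fibre_network(list(poly_between(c(10, 0), c(10, 100))), NULL,
                     c(120L, 120L))
  expect_equal(total_length(h), 100, tolerance = 0.5)
  d <- fibre_network(list(poly_between(c(0, 0), c(100, 100))), NULL,
                     c(120L, 120L))
  expect_equal(total_length(d), 100 * sqrt(2), tolerance = 1)
  empty <- fibre_network(list(), NULL, c(64L, 64L))
  expect_equal(total_length(empty), 0)
  cal <- fibre_network(list(poly_between(c(10, 0), c(10, 100))), NULL,
                       c(120L, 120L), pixel_size_um = 0.5)
  expect_equal(total_length(cal), 50, tolerance = 0.25)
})

test_that("hgu is length per end point, inverse of the normalised end-point metric", {
  expect_equal(hgu(2, 100), 50)
  expect_true(is.na(hgu(0, 100)))
  expect_equal(hgu(4, 200), hgu(2, 100))      # scale invariance
  expect_equal(hgu(2, 100, convention = "per_length"), 1 / hgu(2, 100))
  rec <- normalise_record(data.frame(endpoints = 2L, branchpoints = 0L,
                                     total_length = 100), 1e4)
  expect_equal(rec$norm_endpoints, 1 / hgu(2, 100))
})

test_that("average fibre length and thickness follow their defining ratios", {
  expect_equal(avg_fibre_length(100, 2, 0), 100)
  expect_equal(avg_fibre_length(120, 3, 1), 60)
  expect_true(is.na(avg_fibre_length(50, 0, 0)))
  expect_equal(fibre_thickness(400, 100), 4)
  expect_true(is.na(fibre_thickness(400, 0)))
  expect_equal(fibre_thickness(800, 100), 2 * fibre_thickness(400, 100))
  # rendered geometry: a 100 px line of width 4 covers ~400 px of matrix
  v <- cbind(rep(64, 100), seq(14, 113, length.out = 100))
  img <- gray_image(fibremetrics:::render_polylines(list(v), 128, 4, 0, 255))
  hdm <- compute_hdm(img, 128)
  net <- prune_short_branches(detect_lines(img, ridge_params(4)), 10)
  th <- fibre_thickness(hdm$hdm * 128^2, total_length(net))
  expect_equal(th, 4, tolerance = 0.4)
})

test_that("curvature matches the circle chord closed form and is rotation invariant", {
  for (r in c(40, 60)) {
    phi <- seq(0, 2.5, by = 0.01)
    v <- cbind(150 - r * cos(phi), 60 + r * sin(phi))
    net <- fibre_network(list(v), NULL, c(256L, 256L))
    for (w in c(10, 20)) {
      expect_equal(curvature(net, w), 2 * asin(w / (2 * r)) * 180 / pi,
                   tolerance = 0.5)
    }
  }
  straight <- fibre_network(list(poly_between(c(10, 10), c(200, 150))), NULL,
                            c(256L, 256L))
  expect_equal(curvature(straight, 10), 0, tolerance = 1e-6)
  # rigid rotation leaves curvature unchanged
  phi <- seq(0, 2, by = 0.01)
  v <- cbind(150 - 50 * cos(phi), 80 + 50 * sin(phi))
  th <- 23 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  vr <- sweep(sweep(v, 2, c(128, 128)) %*% R, 2, c(128, 128), `+`)
  n1 <- fibre_network(list(v), NULL, c(256L, 256L))
  n2 <- fibre_network(list(vr), NULL, c(256L, 256L))
  expect_equal(curvature(n2, 15), curvature(n1, 15), tolerance = 0.5)
  expect_error(curvature(n1, 1), "window_px")
  short <- fibre_network(list(poly_between(c(10, 10), c(10, 20))), NULL,
                         c(64L, 64L))
  expect_true(is.na(curvature(short, 30)))
})

test_that("curvature sweep reports one value per window and propagates NAs", {
  straight <- fibre_network(list(poly_between(c(10, 10), c(200, 200))), NULL,
                            c(256L, 256L))
  one <- curvature_sweep(straight, 10, 10)
  expect_named(one, "w10")
  sw <- curvature_sweep(straight, 10, 50, 10)
  expect_named(sw, paste0("w", seq(10, 50, 10)))
  expect_true(all(abs(sw) < 1e-4))
  short <- fibre_network(list(poly_between(c(10, 10), c(10, 30))), NULL,
                         c(64L, 64L))
  sw2 <- curvature_sweep(short, 10, 30, 10)
  expect_true(is.na(sw2[["w30"]]))
})

test_that("normalised metrics follow their defining ratios and missing rules", {
  rec <- normalise_record(data.frame(endpoints = 10L, branchpoints = 4L,
                                     total_length = 500), 1024^2)
  expect_equal(rec$norm_endpoints, 0.02)
  expect_equal(rec$norm_branchpoints, 0.008)
  expect_equal(rec$norm_length, 1000 * 500 / 1024^2)
  rec0 <- normalise_record(data.frame(endpoints = 0L, branchpoints = 0L,
                                      total_length = 0), 1024^2)
  expect_true(all(is.na(c(rec0$norm_endpoints, rec0$norm_branchpoints,
                          rec0$norm_length))))
})

test_that("metrics_record assembles raw and normalised columns consistently", {
  y <- make_y_network()
  rec <- metrics_record("toy", y, hdm = 0.1, alignment = 0.5,
                        fractal_dim = 1.2, lacunarity = 2,
                        curvatures = c(w10 = 1.5))
  expect_equal(rec$endpoints, 3L)
  expect_equal(rec$branchpoints, 1L)
  expect_equal(rec$avg_fibre_length, rec$total_length / (0.5 * (3 + 1)))
  expect_equal(rec$hgu, rec$total_length / 3)
  expect_equal(rec$norm_endpoints, rec$endpoints / rec$total_length)
  expect_equal(rec$curvature_w10, 1.5)
})
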