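write_test_scenes <- function(dir, n = 3L, size = 128L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in seq_len(n)) {
    sc <- render_scene(scene_spec(size, n_fibres = 5,
                                  orientation_mode = "aligned",
                                  fibre_width_px = 4, min_separation_px = 12,
                                  length_px = c(40, 90), seed = s))
    write_gray(sc$image, file.path(dir, sprintf("scene%d.png", s)))
  }
}

test_that("parameter files round-trip, default, and validate ranges", {
  p <- parameter_set(line_width_min_px = 4, line_width_max_px = 9,
                     gap_analysis = TRUE)
  expect_s3_class(p, "parameter_set")
  expect_equal(p$min_branch_px, 10)          # untouched default
  f <- tempfile(fileext = ".txt")
  write_parameters(p, f)
  p2 <- load_parameters(f)
  expect_equal(unclass(p2), unclass(p))

  f2 <- tempfile()
  writeLines(c("# only widths", "line_width_min_px = 6",
               "line_width_max_px = 6"), f2)
  p3 <- load_parameters(f2)
  expect_equal(p3$line_width_min_px, 6)
  expect_equal(p3$hdm_threshold, 185)

  expect_error(parameter_set(line_width_min_px = 20, line_width_max_px = 5),
               "line_width_min_px")
  expect_warning(parameter_set(bogus_key = 1), "bogus_key")
  f3 <- tempfile()
  writeLines("curvature_window_min_px = 50", f3)
  expect_error(load_parameters(f3), "curvature_window")
})

test_that("process_image runs the full pipeline against generator truth", {
  sc <- render_scene(scene_spec(192, n_fibres = 12,
                                orientation_mode = "aligned", jitter_deg = 5,
                                fibre_width_px = 4, min_separation_px = 12,
                                length_px = c(60, 120), seed = 14))
  params <- parameter_set(line_width_min_px = 4, line_width_max_px = 4)
  res <- process_image(sc$image, params, image_id = "aligned")
  rec <- res$record
  expect_gt(rec$alignment, 0.8)
  expect_equal(rec$endpoints, sc$truth$endpoints, tolerance = 0.1 * sc$truth$endpoints)
  expect_equal(rec$total_length, sc$truth$total_length_px,
               tolerance = 0.1 * sc$truth$total_length_px)
  expect_equal(rec$branchpoints, 0, tolerance = 1)

  blank <- gray_image(matrix(10, 128, 128))
  suppressWarnings(res0 <- process_image(blank, params, image_id = "blank"))
  expect_equal(res0$record$total_length, 0)
  expect_equal(res0$record$endpoints, 0L)
  expect_true(is.na(res0$record$fractal_dim))
  expect_true(is.na(res0$record$hgu))
})

test_that("batch runs are deterministic, log failures, and version outputs", {
  indir <- file.path(tempdir(), "fm_in")
  unlink(indir, recursive = TRUE)
  write_test_scenes(indir, 3L)
  writeLines("not an image", file.path(indir, "corrupt.png"))
  params <- parameter_set(line_width_min_px = 4, line_width_max_px = 4,
                          gap_analysis = TRUE, min_gap_diameter_px = 8)

  od1 <- file.path(tempdir(), "fm_out1"); unlink(od1, recursive = TRUE)
  od2 <- file.path(tempdir(), "fm_out2"); unlink(od2, recursive = TRUE)
  r1 <- run_batch(indir, params, od1)
  r2 <- run_batch(indir, params, od2)
  expect_equal(nrow(r1$summary), 3L)
  expect_equal(r1$n_failed, 1L)
  expect_named(r1$failures, "corrupt.png")
  expect_identical(readLines(r1$summary_csv), readLines(r2$summary_csv))
  expect_true(all(c("norm_endpoints", "norm_length", "gap_count",
                    "curvature_w10") %in% names(r1$summary)))
  expect_true(file.exists(file.path(od1, "scene1_mask.png")))
  expect_true(file.exists(file.path(od1, "scene1_gaps.csv")))
  expect_true(any(grepl("FAILED", readLines(r1$log))))

  # rerun into the same directory: previous outputs versioned, not clobbered
  r3 <- run_batch(indir, params, od1)
  expect_true(file.exists(file.path(od1, "summary.csv.1")))
  expect_identical(readLines(file.path(od1, "summary.csv")),
                   readLines(file.path(od1, "summary.csv.1")))

  expect_error(run_batch(file.path(tempdir(), "nope_dir"), params, od1),
               "no eligible")
})

test_that("prechecks and cropping behave", {
  indir <- file.path(tempdir(), "fm_pre")
  unlink(indir, recursive = TRUE)
  write_test_scenes(indir, 1L)
  write_gray(gray_image(matrix(99, 64, 64)), file.path(indir, "flat.png"))
  pc <- precheck_images(indir)
  expect_equal(nrow(pc), 2L)
  expect_false(pc$eligible[pc$file == "flat.png"])
  expect_true(pc$eligible[pc$file == "scene1.png"])

  img <- gray_image(matrix(seq_len(64 * 64) %% 256, 64, 64))
  cr <- crop_image(img, c(10, 5, 41, 36))
  expect_equal(dim(unclass(cr)), c(32L, 32L))
  expect_error(crop_image(img, c(0, 1, 70, 70)), "ROI")
})

test_that("fixture emission writes images plus machine-readable truth", {
  fd <- file.path(tempdir(), "fm_fix")
  unlink(fd, recursive = TRUE)
  emit_fixtures(fd, size = 96, seed = 3)
  expect_true(all(file.exists(file.path(
    fd, c("aligned.png", "isotropic.png", "stripes.png", "rings.png",
          "grid.png", "truth.csv")))))
  tr <- read.csv(file.path(fd, "truth.csv"))
  expect_equal(nrow(tr), 2L)
  expect_true(all(tr$endpoints == 2 * tr$n_fibres))
  img <- read_gray(file.path(fd, "aligned.png"))
  expect_equal(dim(unclass(img)), c(96L, 96L))
})

test_that("image files round-trip through write_gray/read_gray", {
  img <- gray_image(matrix(sample(0:255, 64 * 64, TRUE), 64, 64))
  for (ext in c(".png", ".tif")) {
    f <- tempfile(fileext = ext)
    write_gray(img, f)
    back <- read_gray(f)
    expect_equal(unclass(back), unclass(img), tolerance = 0.5,
                 ignore_attr = TRUE)
  }
})
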