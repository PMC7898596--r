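ridge_params_from <- function(params) {
  ridge_params(line_width_min_px = params$line_width_min_px,
               line_width_max_px = params$line_width_max_px,
               min_branch_px = params$min_branch_px,
               dark_lines = params$dark_lines)
}

#' Process a single image through the full pipeline
#'
#' Preprocessing (polarity normalisation, contrast saturation, HDM), ridge
#' detection at the configured line width(s) with mask amalgamation, network
#' metrics on the minimum-width network, global pattern metrics (alignment
#' on the grayscale image; fractal dimension and lacunarity on the
#' amalgamated mask), and optional gap analysis. When an output directory is
#' given, the mask(s), HDM image and per-image gap CSV are written there.
#'
#' Network metrics are computed from the detection pass at the minimum line
#' width (the amalgamated mask serves the mask-based pattern metrics only),
#' so counts refer to a single, stated detection scale.
#'
#' @param img a [gray_image()], or a path to an image file.
#' @param params a [parameter_set()].
#' @param image_id identifier used in the output row (defaults to the file
#'   name, or `"image"`).
#' @param output_dir optional directory for per-image artefacts.
#' @return list with `record` (one-row metrics data frame), `network`,
#'   `mask`, `hdm_mask`, `gap_circles` (or `NULL`), `artefacts` (paths).
#' @export
process_image <- function(img, params = parameter_set(), image_id = NULL,
                          output_dir = NULL) {
  if (is.character(img)) {
    if (is.null(image_id)) image_id <- basename(img)
    ps <- params$pixel_size_um
    img <- read_gray(img, pixel_size_um = if (is.na(ps)) NULL else ps)
  } else if (is.null(image_id)) image_id <- "image"

  img <- normalise_polarity(img, params$dark_lines)
  img <- contrast_saturate(img, params$contrast_saturation_pct)
  hdm_res <- compute_hdm(img, params$hdm_threshold)

  det <- detect_multiscale(img, ridge_params_from(params))
  net <- det$networks[[1L]]   # minimum line width pass

  curv <- if (length(net$fibres)) {
    curvature_sweep(net, params$curvature_window_min_px,
                    params$curvature_window_max_px,
                    params$curvature_window_step_px)
  } else NULL
  align <- alignment_from_image(img)
  fd <- fractal_dimension(det$mask)
  lac <- lacunarity(det$mask)

  circles <- NULL; gstats <- NULL
  if (isTRUE(params$gap_analysis)) {
    circles <- max_inscribed_circles(det$mask, params$min_gap_diameter_px)
    gstats <- gap_statistics(circles)
  }

  rec <- metrics_record(image_id, net, hdm = hdm_res$hdm,
                        alignment = align, fractal_dim = fd,
                        lacunarity = lac, curvatures = curv,
                        gap_stats = gstats)

  artefacts <- character(0)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- tools::file_path_sans_ext(image_id)
    p_mask <- file.path(output_dir, paste0(stem, "_mask.png"))
    write_gray(det$mask, p_mask)
    p_hdm <- file.path(output_dir, paste0(stem, "_hdm.png"))
    write_gray(hdm_res$mask, p_hdm)
    artefacts <- c(mask = p_mask, hdm = p_hdm)
    if (length(det$masks) > 1L) {
      for (w in names(det$masks)) {
        pw <- file.path(output_dir, paste0(stem, "_mask_w", w, ".png"))
        write_gray(det$masks[[w]], pw)
        artefacts <- c(artefacts, pw)
      }
    }
    if (!is.null(circles)) {
      p_gap <- file.path(output_dir, paste0(stem, "_gaps.csv"))
      write_gap_csv(circles, p_gap)
      artefacts <- c(artefacts, gaps = p_gap)
    }
  }

  list(record = rec, network = net, mask = det$mask, hdm_mask = hdm_res$mask,
       gap_circles = circles, artefacts = artefacts)
}

version_existing <- function(path) {
  if (!file.exists(path)) return(invisible(NULL))
  k <- 1L
  repeat {
    cand <- sprintf("%s.%d", path, k)
    if (!file.exists(cand)) { file.rename(path, cand); break }
    k <- k + 1L
  }
  invisible(NULL)
}

#' Round floating-point columns for stable CSV output
#' @noRd
format_summary <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  df
}

#' Run a batch of images
#'
#' Processes every readable TIFF/PNG/JPEG in `input_dir` with a fixed
#' parameter set, writing one summary CSV (one row per image, sorted by
#' file name), per-image artefacts, and a plain-text log that includes the
#' parameter set. Unreadable images are logged as failures and skipped, not
#' silently dropped; existing outputs are versioned, never clobbered.
#' Floating-point columns are rounded to 6 significant digits at write time,
#' so identical inputs and parameters give byte-identical CSVs.
#'
#' @param input_dir directory of input images.
#' @param params a [parameter_set()].
#' @param output_dir output directory (created if needed).
#' @return invisibly, a list: `summary` (data frame), `summary_csv`,
#'   `failures` (named character vector of error messages), `log` (path),
#'   `n_ok`, `n_failed`.
#' @export
run_batch <- function(input_dir, params = parameter_set(), output_dir) {
  files <- sort(list.files(input_dir,
                           pattern = "\\.(tif|tiff|png|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no eligible image files in ", input_dir)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  loglines <- c("fibremetrics batch run",
                paste0("input_dir: ", input_dir),
                "parameters:",
                vapply(names(params), function(nm)
                  sprintf("  %s = %s", nm, format(params[[nm]])),
                  character(1)))
  rows <- list(); failures <- character(0)
  for (f in files) {
    res <- tryCatch(process_image(f, params, output_dir = output_dir),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[basename(f)] <- conditionMessage(res)
      loglines <- c(loglines,
                    sprintf("FAILED  %s: %s", basename(f),
                            conditionMessage(res)))
    } else {
      rows[[basename(f)]] <- res$record
      loglines <- c(loglines, sprintf("ok      %s", basename(f)))
    }
  }
  if (!length(rows)) stop("all images failed; see log")
  # union of columns across rows (gap columns may be absent on failure modes)
  allcols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) {
    for (nm in setdiff(allcols, names(r))) r[[nm]] <- NA
    r[allcols]
  })
  summary <- do.call(rbind, rows[order(names(rows))])
  rownames(summary) <- NULL

  summary_csv <- file.path(output_dir, "summary.csv")
  version_existing(summary_csv)
  utils::write.csv(format_summary(summary), summary_csv, row.names = FALSE)
  logpath <- file.path(output_dir, "run.log")
  version_existing(logpath)
  writeLines(c(loglines,
               sprintf("processed %d, failed %d", length(rows),
                       length(failures))), logpath)
  invisible(list(summary = summary, summary_csv = summary_csv,
                 failures = failures, log = logpath,
                 n_ok = length(rows), n_failed = length(failures)))
}

#' Eligibility report for candidate input images
#'
#' Non-interactive prechecks: each file must be readable, at least 16 px in
#' both dimensions, and not constant.
#'
#' @param input_dir directory of candidate images.
#' @return data frame with columns `file`, `eligible`, `reason`.
#' @export
precheck_images <- function(input_dir) {
  files <- sort(list.files(input_dir,
                           pattern = "\\.(tif|tiff|png|jpg|jpeg)$",
                           ignore.case = TRUE, full.names = TRUE))
  res <- lapply(files, function(f) {
    img <- tryCatch(read_gray(f), error = function(e) e)
    if (inherits(img, "error"))
      return(data.frame(file = basename(f), eligible = FALSE,
                        reason = conditionMessage(img)))
    if (max(img) - min(img) < 1e-9)
      return(data.frame(file = basename(f), eligible = FALSE,
                        reason = "constant image"))
    data.frame(file = basename(f), eligible = TRUE, reason = "")
  })
  do.call(rbind, res)
}

#' Crop an image to a rectangular region of interest
#'
#' @param img a [gray_image()].
#' @param roi integer vector `c(row_min, col_min, row_max, col_max)`.
#' @return the cropped [gray_image()].
#' @export
crop_image <- function(img, roi) {
  if (length(roi) != 4L) stop("`roi` must be c(row_min, col_min, row_max, col_max)")
  if (roi[1L] < 1 || roi[2L] < 1 || roi[3L] > nrow(img) || roi[4L] > ncol(img) ||
      roi[1L] > roi[3L] || roi[2L] > roi[4L])
    stop("ROI lies outside the image")
  gray_image(unclass(img)[roi[1L]:roi[3L], roi[2L]:roi[4L]],
             pixel_size_um = pixel_size(img))
}

#' Emit a synthetic fixture set
#'
#' Writes a small set of validation images with machine-readable ground
#' truth: an aligned and an isotropic fibre field, a grating, a ring
#' pattern, and a grid mask, plus `truth.csv` summarising the generator
#' truth for the fibre fields.
#'
#' @param out_dir output directory.
#' @param size image side, px.
#' @param seed RNG seed.
#' @return invisibly, the paths written.
#' @export
emit_fixtures <- function(out_dir, size = 256, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  sc_a <- render_scene(scene_spec(image_size_px = size, n_fibres = 20,
                                  orientation_mode = "aligned",
                                  jitter_deg = 5, seed = seed))
  sc_i <- render_scene(scene_spec(image_size_px = size, n_fibres = 20,
                                  orientation_mode = "isotropic",
                                  seed = seed + 1L))
  truth <- rbind(
    data.frame(image = "aligned.png", n_fibres = sc_a$truth$n_pieces,
               endpoints = sc_a$truth$endpoints,
               branchpoints = sc_a$truth$branchpoints,
               total_length_px = sc_a$truth$total_length_px),
    data.frame(image = "isotropic.png", n_fibres = sc_i$truth$n_pieces,
               endpoints = sc_i$truth$endpoints,
               branchpoints = sc_i$truth$branchpoints,
               total_length_px = sc_i$truth$total_length_px))
  for (nm in c("aligned", "isotropic")) {
    p <- file.path(out_dir, paste0(nm, ".png"))
    write_gray(if (nm == "aligned") sc_a$image else sc_i$image, p)
    paths <- c(paths, p)
  }
  extras <- list(stripes = unclass(make_stripes(size)),
                 rings = unclass(make_rings(size)),
                 grid = make_grid(size, 32))
  for (nm in names(extras)) {
    p <- file.path(out_dir, paste0(nm, ".png"))
    write_gray(extras[[nm]], p)
    paths <- c(paths, p)
  }
  tp <- file.path(out_dir, "truth.csv")
  utils::write.csv(truth, tp, row.names = FALSE)
  invisible(c(paths, tp))
}
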