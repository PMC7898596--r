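PARAM_DEFAULTS <- list(
  contrast_saturation_pct = 0.35,
  line_width_min_px = 5,
  line_width_max_px = 5,
  min_branch_px = 10,
  curvature_window_min_px = 10,
  curvature_window_max_px = 40,
  curvature_window_step_px = 10,
  min_gap_diameter_px = 10,
  hdm_threshold = 185,
  dark_lines = FALSE,
  gap_analysis = FALSE,
  pixel_size_um = NA_real_
)

#' Batch parameter set
#'
#' All user-tunable parameters of a batch run, with the documented defaults
#' applied to any not given. Persisted verbatim by [write_parameters()] so
#' runs are reproducible.
#'
#' @param ... named parameters overriding the defaults; see Details.
#' @details Parameters (all lengths in pixels on the input image):
#' * `contrast_saturation_pct`: percent of pixels clipped by the contrast
#'   stretch (default 0.35).
#' * `line_width_min_px`, `line_width_max_px`: fibre width range for ridge
#'   detection (default 5/5; ranges are swept in increments of 5).
#' * `min_branch_px`: minimum branch length, shorter dangling branches are
#'   pruned (default 10).
#' * `curvature_window_min_px`, `curvature_window_max_px`,
#'   `curvature_window_step_px`: curvature window sweep (default 10..40
#'   step 10).
#' * `min_gap_diameter_px`: smallest gap diameter reported (default 10).
#' * `hdm_threshold`: intensity threshold for the high-density-matrix
#'   fraction on the post-saturation 8-bit scale (default 185), or `"otsu"`.
#' * `dark_lines`: `TRUE` when fibres are dark on a light background.
#' * `gap_analysis`: enable inscribed-circle gap analysis.
#' * `pixel_size_um`: microns per pixel (`NA` = report in pixels).
#' @return object of class `parameter_set`.
#' @export
parameter_set <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all parameters must be named")
  unknown <- setdiff(names(over), names(PARAM_DEFAULTS))
  if (length(unknown))
    warning("unknown parameter(s) ignored: ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(PARAM_DEFAULTS, over[setdiff(names(over), unknown)])
  validate_params(p)
  structure(p, class = "parameter_set")
}

validate_params <- function(p) {
  chk_range <- function(lo, hi, key) {
    if (p[[lo]] > p[[hi]])
      stop(sprintf("invalid range: %s (%s) exceeds %s (%s)",
                   lo, p[[lo]], hi, p[[hi]]))
  }
  chk_range("line_width_min_px", "line_width_max_px", "line width")
  chk_range("curvature_window_min_px", "curvature_window_max_px",
            "curvature window")
  if (p$line_width_min_px <= 0) stop("line widths must be positive")
  if (p$contrast_saturation_pct < 0 || p$contrast_saturation_pct >= 100)
    stop("contrast_saturation_pct must lie in [0, 100)")
  if (p$curvature_window_step_px < 1)
    stop("curvature_window_step_px must be >= 1")
  if (p$min_gap_diameter_px <= 0) stop("min_gap_diameter_px must be positive")
  if (!identical(p$hdm_threshold, "otsu") &&
      (p$hdm_threshold < 0 || p$hdm_threshold > 255))
    stop("hdm_threshold must lie in [0, 255] or be \"otsu\"")
  invisible(p)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("parameter_set:\n")
  for (nm in names(x)) cat(sprintf("  %s = %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a parameter file
#'
#' Flat `key = value` text (one per line, `#` comments). Absent keys take
#' the documented defaults; unknown keys give a warning; an invalid range
#' (minimum above maximum) is an error naming the key.
#'
#' @param path path to the parameter file.
#' @return a [parameter_set()].
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L) stop("malformed parameter line: ", ln)
    key <- trimws(parts[1L]); val <- trimws(parts[2L])
    kv[[key]] <- parse_param_value(key, val)
  }
  do.call(parameter_set, kv)
}

parse_param_value <- function(key, val) {
  if (key %in% c("dark_lines", "gap_analysis"))
    return(toupper(val) %in% c("TRUE", "T", "YES", "1"))
  if (key == "hdm_threshold" && tolower(val) == "otsu") return("otsu")
  if (toupper(val) %in% c("NA", "NONE")) return(NA_real_)
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) stop("cannot parse value for ", key, ": ", val)
  num
}

#' Write a parameter file
#'
#' Inverse of [load_parameters()]; `load_parameters(write_parameters(p, f))`
#' reproduces `p`.
#'
#' @param params a [parameter_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  lines <- vapply(names(params), function(nm) {
    v <- params[[nm]]
    v <- if (is.logical(v)) as.character(v) else format(v, digits = 15)
    sprintf("%s = %s", nm, v)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
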