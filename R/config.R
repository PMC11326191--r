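#' Validate a pipeline run configuration
#'
#' Reads a YAML run configuration, applies defaults, and checks every field,
#' reporting *all* problems at once rather than stopping at the first. The
#' configuration drives [run_pipeline()]; see the package vignette for the
#' full schema.
#'
#' @param path Path to a YAML file, or a pre-parsed named list.
#' @return An object of class `qdf_config` (a validated named list with
#'   defaults filled in). On any validation failure an error is signalled
#'   whose message lists every problem found.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stop("path must be a file or a list")
  errs <- character(0)
  note <- function(msg) errs <<- c(errs, msg)

  cfg <- list(
    input_dir = raw$input_dir,
    output_dir = raw$output_dir,
    reference = raw$reference,
    c = raw$c %||% "auto",
    calibration = raw$calibration,
    bit_divisor = raw$bit_divisor %||% 16,
    background_degree = raw$background_degree %||% 8,
    reference_mode = raw$reference_mode %||% "per_quadrant",
    wavelength = raw$wavelength %||% 0.532,
    pixel_size = raw$pixel_size %||% 0.586,
    alpha = raw$alpha %||% 1.8e-4,
    segmentation = utils::modifyList(
      list(min_area = 50, h_depth = 0.15, smooth_sigma = 1, dilate_px = 5),
      raw$segmentation %||% list()),
    tracking = utils::modifyList(list(max_disp = 20, memory = 0),
                                 raw$tracking %||% list()),
    debris = raw$debris,
    snr = utils::modifyList(list(k = 4, q = 99), raw$snr %||% list()),
    seed = raw$seed %||% 1L)

  if (is.null(cfg$input_dir)) note("input_dir: missing")
  else if (!dir.exists(cfg$input_dir))
    note(paste0("input_dir: directory does not exist: ", cfg$input_dir))
  if (is.null(cfg$output_dir)) note("output_dir: missing")
  if (!is.null(cfg$reference) && !file.exists(cfg$reference))
    note(paste0("reference: file does not exist: ", cfg$reference))
  if (identical(cfg$c, "auto")) {
    if (is.null(cfg$calibration) ||
        is.null(cfg$calibration$position) || is.null(cfg$calibration$timepoint))
      note("c: 'auto' requires a calibration field naming position and timepoint")
  } else if (!is.numeric(cfg$c) || length(cfg$c) != 1 || cfg$c <= 0) {
    note("c: must be 'auto' or a positive number")
  }
  if (!is.numeric(cfg$bit_divisor) || cfg$bit_divisor < 1)
    note("bit_divisor: must be >= 1")
  if (!is.numeric(cfg$background_degree) || cfg$background_degree < 0 ||
      cfg$background_degree > 8)
    note("background_degree: must be between 0 and 8")
  if (!cfg$reference_mode %in% c("per_quadrant", "darkfield"))
    note("reference_mode: must be 'per_quadrant' or 'darkfield'")
  if (!is.numeric(cfg$wavelength) || cfg$wavelength <= 0)
    note("wavelength: must be positive (um)")
  if (!is.numeric(cfg$pixel_size) || cfg$pixel_size <= 0)
    note("pixel_size: must be positive (um)")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0)
    note("alpha: must be positive (m^3/kg)")
  if (cfg$segmentation$min_area < 0) note("segmentation.min_area: must be >= 0")
  if (cfg$segmentation$h_depth <= 0) note("segmentation.h_depth: must be > 0")
  if (!is.numeric(cfg$tracking$max_disp) || cfg$tracking$max_disp <= 0)
    note("tracking.max_disp: must be > 0")
  if (cfg$tracking$memory < 0) note("tracking.memory: must be >= 0")
  if (!is.null(cfg$debris)) {
    allowed <- c("area", "track_length", "mean_phase", "mean_df", "mean_qdf")
    bad <- setdiff(names(cfg$debris), allowed)
    if (length(bad))
      note(paste0("debris: unknown metric(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.numeric(cfg$seed)) note("seed: must be an integer")

  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(cfg, class = "qdf_config")
}

#' @export
print.qdf_config <- function(x, ...) {
  cat("QDF pipeline configuration\n")
  cat("  input : ", x$input_dir, "\n", sep = "")
  cat("  output: ", x$output_dir, "\n", sep = "")
  cat(sprintf("  c = %s, degree = %d, divisor = %d, pixel %g um, lambda %g um\n",
              if (identical(x$c, "auto")) "auto" else format(x$c),
              x$background_degree, x$bit_divisor, x$pixel_size, x$wavelength))
  invisible(x)
}
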