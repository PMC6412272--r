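#' Run configuration
#'
#' Builds the configuration object consumed by the pre-processing, texture
#' and classification stages. All parameters default to the values used
#' throughout the package; any subset can be overridden.
#'
#' @param disk_radius radius in pixels of the disk structuring element used
#'   by the morphological opening. Default 3 (at 400 x 300 scale).
#' @param small_area_fraction fraction of the largest connected-component
#'   area used as the small-region threshold; components with area strictly
#'   greater than `small_area_fraction * max_area` are kept. In (0, 1],
#'   default 0.1.
#' @param connectivity pixel connectivity for region labeling, 4 or 8.
#'   Default 8.
#' @param glcm_levels number of gray levels used for GLCM quantization
#'   (>= 2). Default 16.
#' @param glcm_distance co-occurrence step in pixels (>= 1). Default 2.
#' @param glcm_angles directions in degrees along which co-occurrences are
#'   counted. Default c(0, 45, 90, 135).
#' @param feature_set character subset of
#'   c("contrast", "entropy", "correlation") forming the classifier feature
#'   vector. Default c("contrast", "entropy").
#' @param entropy_log_base base of the logarithm in the GLCM entropy, 2 or
#'   exp(1). Default 2 (bits).
#' @param binarize_polarity "bright" thresholds foreground as pixel > t
#'   (warm-palette fruit are bright in the red channel); "dark" inverts.
#' @param glcm_masked if TRUE, co-occurrence pairs with either endpoint
#'   outside the region mask are excluded; by default the full bounding
#'   rectangle (including zero background) is counted.
#' @param seed integer seed for operations that draw random numbers.
#' @return an object of class `msx_config` (a named list).
#' @export
msx_config <- function(disk_radius = 3,
                       small_area_fraction = 0.1,
                       connectivity = 8,
                       glcm_levels = 16,
                       glcm_distance = 2,
                       glcm_angles = c(0, 45, 90, 135),
                       feature_set = c("contrast", "entropy"),
                       entropy_log_base = 2,
                       binarize_polarity = "bright",
                       glcm_masked = FALSE,
                       seed = 1L) {
  cfg <- list(
    disk_radius = disk_radius,
    small_area_fraction = small_area_fraction,
    connectivity = connectivity,
    glcm_levels = glcm_levels,
    glcm_distance = glcm_distance,
    glcm_angles = glcm_angles,
    feature_set = feature_set,
    entropy_log_base = entropy_log_base,
    binarize_polarity = binarize_polarity,
    glcm_masked = glcm_masked,
    seed = seed
  )
  class(cfg) <- "msx_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, key, why) {
    if (!ok) msx_stop_validation("config key '", key, "': ", why)
  }
  chk(is.numeric(cfg$disk_radius) && length(cfg$disk_radius) == 1 &&
        cfg$disk_radius >= 0, "disk_radius", "must be a single number >= 0")
  chk(is.numeric(cfg$small_area_fraction) &&
        cfg$small_area_fraction > 0 && cfg$small_area_fraction <= 1,
      "small_area_fraction", "must be in (0, 1]")
  chk(length(cfg$connectivity) == 1 && cfg$connectivity %in% c(4, 8),
      "connectivity", "must be 4 or 8")
  chk(is.numeric(cfg$glcm_levels) && cfg$glcm_levels >= 2 &&
        cfg$glcm_levels == round(cfg$glcm_levels),
      "glcm_levels", "must be an integer >= 2")
  chk(is.numeric(cfg$glcm_distance) && cfg$glcm_distance >= 1,
      "glcm_distance", "must be >= 1")
  chk(length(cfg$glcm_angles) >= 1 &&
        all(cfg$glcm_angles %in% c(0, 45, 90, 135)),
      "glcm_angles", "must be a non-empty subset of {0, 45, 90, 135}")
  chk(length(cfg$feature_set) >= 1 &&
        all(cfg$feature_set %in% c("contrast", "entropy", "correlation")),
      "feature_set",
      "must be a non-empty subset of {contrast, entropy, correlation}")
  chk(length(cfg$entropy_log_base) == 1 &&
        (cfg$entropy_log_base == 2 || abs(cfg$entropy_log_base - exp(1)) < 1e-12),
      "entropy_log_base", "must be 2 or e")
  chk(cfg$binarize_polarity %in% c("bright", "dark"),
      "binarize_polarity", "must be 'bright' or 'dark'")
  chk(is.logical(cfg$glcm_masked) && length(cfg$glcm_masked) == 1,
      "glcm_masked", "must be TRUE or FALSE")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 &&
        cfg$seed == round(cfg$seed), "seed", "must be a single integer")
  invisible(cfg)
}

#' Load a run configuration from YAML or JSON
#'
#' Missing keys are filled with the [msx_config()] defaults; unknown keys
#' are rejected. The format is chosen by file extension (`.yaml`/`.yml`
#' vs `.json`).
#'
#' @param path path to a YAML or JSON configuration file.
#' @return an `msx_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) msx_stop_io("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
    else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
    else msx_stop_validation("unsupported config format: .", ext),
    error = function(e) {
      if (inherits(e, "msx_error")) stop(e)
      msx_stop_io("cannot parse config file ", path, ": ", conditionMessage(e))
    }
  )
  if (is.null(raw)) raw <- list()   # empty file -> all defaults
  known <- names(formals(msx_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    msx_stop_validation("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(msx_config, raw)
}

#' Write a run configuration
#' @param cfg an `msx_config` object.
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else msx_stop_validation("unsupported config format: .", ext)
  invisible(path)
}

#' @export
print.msx_config <- function(x, ...) {
  cat("MSX run configuration\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, paste(x[[k]], collapse = " ")))
  invisible(x)
}
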