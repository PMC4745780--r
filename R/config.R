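#' Default run configuration
#'
#' Single source of truth for every tunable of the pipeline. Values are the
#' package defaults; any subset may be overridden from a YAML file via
#' [load_config()]. Windows are full widths in pixels and must be odd;
#' `fibro$block_halfwidth` is the half-width k of the (2k+1) x (2k+1)
#' adaptive-threshold block.
#'
#' @return nested list of configuration values.
#' @export
default_config <- function() {
  list(
    preprocess = list(
      median_window   = 5,    # median filter window (odd)
      nlm_patch       = 7,    # non-local means patch size (odd)
      nlm_search      = 31,   # non-local means search window (odd)
      nlm_h           = 15,   # NLM weight-decay parameter
      ms_spatial_radius = 10, # mean-shift spatial radius (px)
      ms_range_radius   = 10, # mean-shift range radius (intensity units)
      entropy_radius    = 5   # local entropy disc radius (px)
    ),
    stabilize = list(
      method   = "standard",  # "standard" | "blur_robust"
      window   = "hann",      # "hann" | "none"
      subpixel = TRUE,
      channel  = "phase"
    ),
    fibro = list(
      block_halfwidth = 25,   # k; block is (2k+1) x (2k+1)
      sigma           = NA,   # Gaussian width; NA -> (2k+1)/6
      kappa           = 2,    # constant subtracted from the weighted mean
      min_area        = 50    # smallest surviving component (px)
    ),
    flow = list(
      levels     = 3,
      window     = 15,
      iterations = 3,
      poly_n     = 5,
      poly_sigma = 1.1
    ),
    shape = list(
      depth_threshold = 5     # convexity-defect depth for a real extension
    ),
    tumor = list(
      block_halfwidth = 25,
      sigma           = NA,
      kappa           = 2,
      min_area        = 50,
      smooth_radius   = 3     # disc radius for closing/opening
    ),
    mrf = list(
      lambda0     = 0.5,
      lambda1     = 2.0,
      beta        = 0.05,     # on 8-bit intensities
      restarts    = 5,
      max_sweeps  = 10,
      entropy_radius = 5,
      unary_on    = "entropy" # "entropy" | "raw"
    ),
    morpho = list(
      mean_cell_area   = 250, # px^2 per cell, for the CellNumber estimate
      body_open_radius = 4,   # opening radius separating body vs appendages
      min_app_area     = 5,   # smallest appendage component (px)
      smooth_window    = 5    # centered moving-average window for curves
    ),
    stats = list(
      test = "mannwhitney"    # "mannwhitney" | "ttest"
    )
  )
}

range_rules <- function() {
  list(
    list("preprocess", "median_window", odd = TRUE, min = 3),
    list("preprocess", "nlm_patch", odd = TRUE, min = 1),
    list("preprocess", "nlm_search", odd = TRUE, min = 3),
    list("preprocess", "nlm_h", min = 1e-12),
    list("preprocess", "ms_spatial_radius", min = 1),
    list("preprocess", "ms_range_radius", min = 0),
    list("preprocess", "entropy_radius", min = 1),
    list("fibro", "block_halfwidth", min = 1),
    list("fibro", "kappa"),
    list("fibro", "min_area", min = 0),
    list("flow", "levels", min = 1),
    list("flow", "window", odd = TRUE, min = 3),
    list("flow", "iterations", min = 1),
    list("flow", "poly_n", min = 2),
    list("flow", "poly_sigma", min = 1e-6),
    list("shape", "depth_threshold", min = 0),
    list("tumor", "block_halfwidth", min = 1),
    list("tumor", "kappa"),
    list("tumor", "min_area", min = 0),
    list("tumor", "smooth_radius", min = 1),
    list("mrf", "lambda0", min = 0),
    list("mrf", "lambda1", min = 0),
    list("mrf", "beta", min = 0),
    list("mrf", "restarts", min = 1),
    list("mrf", "max_sweeps", min = 1),
    list("mrf", "entropy_radius", min = 1),
    list("morpho", "mean_cell_area", min = 1e-9),
    list("morpho", "body_open_radius", min = 1),
    list("morpho", "min_app_area", min = 0),
    list("morpho", "smooth_window", odd = TRUE, min = 1)
  )
}

#' Validate a run configuration
#'
#' Checks every numeric tunable against its documented range; window sizes
#' must be odd. Errors name the offending key and the allowed range.
#'
#' @param config nested configuration list.
#' @return the validated config, invisibly.
#' @export
validate_config <- function(config) {
  for (rule in range_rules()) {
    mod <- rule[[1]]; key <- rule[[2]]
    v <- config[[mod]][[key]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) next
    if (!is.numeric(v) || length(v) != 1)
      stopf("config %s$%s must be a single number", mod, key)
    if (!is.null(rule$min) && v < rule$min)
      stopf("config %s$%s = %s out of range (must be >= %s)",
            mod, key, format(v), format(rule$min))
    if (isTRUE(rule$odd) && !is_odd(v))
      stopf("config %s$%s = %s invalid (window sizes must be odd)",
            mod, key, format(v))
  }
  if (!config$stabilize$method %in% c("standard", "blur_robust"))
    stopf("config stabilize$method must be 'standard' or 'blur_robust'")
  if (!config$mrf$unary_on %in% c("entropy", "raw"))
    stopf("config mrf$unary_on must be 'entropy' or 'raw'")
  with(config$preprocess, if (nlm_patch > nlm_search)
    stopf("config preprocess$nlm_patch must be <= nlm_search"))
  invisible(config)
}

merge_config <- function(base, override, path = "") {
  for (k in names(override)) {
    if (!k %in% names(base))
      stopf("unknown config key '%s%s'", path, k)
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(path, k, "$"))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Load a run configuration from a YAML file
#'
#' Keys absent from the file take the [default_config()] values; every
#' value is range-checked on load. An empty file yields all defaults.
#'
#' @param path YAML config path, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("cannot read config '%s'", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}
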