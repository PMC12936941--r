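# Run configuration: defaults, YAML reading, validation.

#' Default run configuration
#'
#' Returns the full nested configuration used by the pipeline: frame
#' interval (5 min), quality filters (|relative length change| <= 15%
#' between consecutive frames, >= 5 consecutive frames, R^2 > 0.8),
#' neighborhood settings (5 um default radius, 5/9/13 um sweep, 10,000
#' permutations), exchange-model constants (K_M = 1 with all
#' concentrations in units of K_M, epsilon = 1, I_C = 20 K_M,
#' mu_wt = 0.70 /h, mu_max_aux = 0.90 /h) and the synthetic-generator
#' block ([synthetic_config()]).
#'
#' @param ... named overrides merged recursively into the defaults,
#'   e.g. `default_config(filters = list(min_frames = 3))`.
#' @return a nested list with class `auxofate_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    frame_interval_min = 5,
    pixel_scale_um_per_px = 0.065,
    filters = list(
      max_rel_length_change = 0.15,
      min_frames = 5L,
      min_r2 = 0.8
    ),
    neighborhood = list(
      radius_um = 5,
      radii_um = c(5, 9, 13),
      n_permutations = 10000L
    ),
    model = list(
      K_M = 1,
      epsilon = 1,
      I_C_factor = 20,
      mu_wt = 0.70,
      mu_max_aux = 0.90
    ),
    synthetic = synthetic_config()
  )
  overrides <- list(...)
  if (length(overrides) > 0L) {
    cfg <- utils::modifyList(cfg, overrides)
  }
  cfg <- validate_config(cfg)
  class(cfg) <- "auxofate_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' Flat sections mirror the configuration structure; values present in the
#' file override the defaults, everything else keeps its default.
#'
#' @param path path to a YAML file.
#' @return a validated configuration list (see [default_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: '%s'", path), call. = FALSE)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  do.call(default_config, user)
}

#' Validate a run configuration
#'
#' @param cfg nested configuration list.
#' @return `cfg`, invisibly usable; stops with a config error otherwise.
#' @export
validate_config <- function(cfg) {
  check_number(cfg$frame_interval_min, "frame_interval_min", positive = TRUE)
  check_number(cfg$pixel_scale_um_per_px, "pixel_scale_um_per_px", positive = TRUE)
  f <- cfg$filters
  check_number(f$max_rel_length_change, "filters$max_rel_length_change", positive = TRUE)
  check_number(f$min_frames, "filters$min_frames", positive = TRUE)
  check_number(f$min_r2, "filters$min_r2", nonneg = TRUE)
  nb <- cfg$neighborhood
  check_number(nb$radius_um, "neighborhood$radius_um", positive = TRUE)
  if (!is.numeric(nb$radii_um) || any(nb$radii_um <= 0)) {
    stop("neighborhood$radii_um must be positive", call. = FALSE)
  }
  if (anyDuplicated(nb$radii_um)) {
    stop("neighborhood$radii_um must be distinct", call. = FALSE)
  }
  check_number(nb$n_permutations, "neighborhood$n_permutations", positive = TRUE)
  if (nb$n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  m <- cfg$model
  check_number(m$K_M, "model$K_M", positive = TRUE)
  check_number(m$epsilon, "model$epsilon", positive = TRUE)
  check_number(m$I_C_factor, "model$I_C_factor", positive = TRUE)
  check_number(m$mu_wt, "model$mu_wt", positive = TRUE)
  check_number(m$mu_max_aux, "model$mu_max_aux", positive = TRUE)
  cfg$synthetic <- validate_synthetic_config(cfg$synthetic)
  cfg
}
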