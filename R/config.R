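# Run configuration: one YAML file drives the pipeline stages. Units in
# the file are mm and mA (the human-facing convention); everything is
# converted to SI on load.

default_run_config <- function() {
  list(
    model = list(
      radii_mm = c(80, 81, 86, 92),
      conductivities_S_per_m = list(scalp = 0.3, skull = 0.006,
                                    csf = 1.79, brain = 0.33),
      edge_length_mm = 13,
      radial_spacing_mm = NULL,   # defaults to edge_length_mm
      n_electrodes = 64L,
      seed = 1L),
    target = list(
      roi_centre_mm = c(0, 0, 72),
      roi_radius_mm = 16,
      roi_file = NULL,          # element-index list overrides the sphere spec
      orientation = NULL,       # fixed [dx, dy, dz] for the whole ROI
      orientation_file = NULL), # per-element CSV override
    constraints = list(
      i_max_mA = 1,
      per_electrode_mA = NULL,    # list(min = ..., max = ...)
      alpha = NULL),
    method = "dirmax_integral",
    sweep = list(nonroi = "integral", n_grid = 40L),
    output_dir = "tesopt-out")
}

#' Read and validate a pipeline run configuration
#'
#' YAML file with sections `model` (radii_mm, conductivities_S_per_m,
#' edge_length_mm, n_electrodes, seed), `target` (roi_centre_mm,
#' roi_radius_mm, optional orientation), `constraints` (i_max_mA,
#' optional per_electrode_mA min/max, optional alpha), `method`, `sweep`
#' (nonroi, n_grid) and `output_dir`. Missing entries take documented
#' defaults; the default conductivities are 0.3 / 0.006 / 1.79 / 0.33 S/m
#' for scalp / skull / CSF / brain.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return validated config list (class `tes_config`).
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  with(cfg, {
    if (length(model$radii_mm) != 4 || any(diff(unlist(model$radii_mm)) <= 0))
      stop("model.radii_mm must be 4 increasing values")
    if (any(unlist(model$conductivities_S_per_m) <= 0))
      stop("conductivities must be positive")
    if (constraints$i_max_mA <= 0) stop("constraints.i_max_mA must be positive")
    if (!sweep$nonroi %in% c("integral", "elementwise"))
      stop("sweep.nonroi must be 'integral' or 'elementwise'")
    ok_methods <- c("dirmax_integral", "dirmax_elementwise", "wls",
                    "scaled_wls", "constrained_wls", "reciprocity",
                    "reciprocity_limited")
    if (!method %in% ok_methods)
      stop("method must be one of: ", paste(ok_methods, collapse = ", "))
  })
  if (is.null(cfg$model$radial_spacing_mm))
    cfg$model$radial_spacing_mm <- cfg$model$edge_length_mm
  class(cfg) <- "tes_config"
  cfg
}
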