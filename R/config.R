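# Central run configuration: every pipeline tunable in one validated
# object, round-trippable through YAML.

vq_defaults <- function() {
  list(
    seed = 1L,
    # preproc
    soma_sigma_um = 1.5,          # blob-enhancement sigma for somas
    process_sigma_um = 0,         # optional pre-smoothing for process Otsu
    dog_sigma_small = 1,          # DoG scales for ISH cell bodies, px
    dog_sigma_large = 4,
    background_disk_radius = 10L, # ISH background subtraction, px
    ac_iterations = 35L,          # active-contour budget
    ac_smoothing = 1L,
    # coloc3d
    connectivity = 26L,           # 3D component connectivity
    soma_floor_um3 = 300,         # components >= floor count as somas
    puncta_min_voxels = 4L,       # puncta mask size filter
    # ish_quant
    cell_area_bounds_um2 = c(20, 400),
    cr_prior = 0.8,               # expected CR+ fraction
    stat_unit = "image",          # statistical unit: image or cell
    # ephys_ppr
    baseline_window_s = 0.05,
    peak_window_s = c(0.001, 0.015),
    fit_window_s = c(0.008, 0.019),
    correct_summation = TRUE,
    moderate_band = 0.1,
    qc_max_access_resistance = 40,
    qc_min_capacitance_pF = 4
  )
}

vq_bounds <- function() {
  list(seed = c(0, 2^31 - 1), soma_sigma_um = c(0.01, 50),
       process_sigma_um = c(0, 50), dog_sigma_small = c(0.1, 100),
       dog_sigma_large = c(0.2, 500), background_disk_radius = c(1, 500),
       ac_iterations = c(0, 1000), ac_smoothing = c(0, 10),
       soma_floor_um3 = c(0, Inf), puncta_min_voxels = c(1, 1e6),
       cr_prior = c(1e-6, 1 - 1e-6), baseline_window_s = c(1e-4, 10),
       moderate_band = c(0, 1), qc_max_access_resistance = c(0, Inf),
       qc_min_capacitance_pF = c(0, Inf))
}

#' Pipeline run configuration
#'
#' Builds a validated configuration holding every tunable of the imaging
#' and electrophysiology pipelines, with documented defaults. Unknown
#' keys and out-of-bounds values are rejected.
#'
#' @param ... named overrides of the defaults (see `vq_config()` output
#'   for the full set).
#' @return A `vq_config` list.
#' @examples
#' cfg <- vq_config(cr_prior = 0.75, connectivity = 6L)
#' cfg$cr_prior
#' @export
vq_config <- function(...) {
  cfg <- vq_defaults()
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(!nzchar(names(over))))
      stop("configuration overrides must be named")
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
}

validate_config <- function(cfg) {
  bounds <- vq_bounds()
  for (nm in names(bounds)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || any(v < bounds[[nm]][1]) || any(v > bounds[[nm]][2]))
      stop("config '", nm, "' out of bounds [",
           paste(bounds[[nm]], collapse = ", "), "]")
  }
  if (!cfg$connectivity %in% c(6L, 18L, 26L))
    stop("config 'connectivity' must be 6, 18 or 26")
  if (!(cfg$dog_sigma_small < cfg$dog_sigma_large))
    stop("config 'dog_sigma_small' must be < 'dog_sigma_large'")
  if (!cfg$stat_unit %in% c("image", "cell"))
    stop("config 'stat_unit' must be 'image' or 'cell'")
  if (length(cfg$peak_window_s) != 2 ||
      !(0 <= cfg$peak_window_s[1] && cfg$peak_window_s[1] < cfg$peak_window_s[2]))
    stop("config 'peak_window_s' must be an increasing pair")
  if (length(cfg$cell_area_bounds_um2) != 2 ||
      !(cfg$cell_area_bounds_um2[1] < cfg$cell_area_bounds_um2[2]))
    stop("config 'cell_area_bounds_um2' must be an increasing pair")
  if (!is.logical(cfg$correct_summation))
    stop("config 'correct_summation' must be logical")
  structure(cfg, class = "vq_config")
}

#' Write a configuration to YAML
#'
#' @param config a [vq_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "vq_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read and validate a configuration from YAML
#'
#' @param path YAML path.
#' @return A validated `vq_config`. Unknown keys are rejected, so the
#'   round trip through [write_config_yaml()] is lossless.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  int_keys <- c("seed", "background_disk_radius", "ac_iterations",
                "ac_smoothing", "connectivity", "puncta_min_voxels")
  for (k in intersect(int_keys, names(raw))) raw[[k]] <- as.integer(raw[[k]])
  do.call(vq_config, raw)
}
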