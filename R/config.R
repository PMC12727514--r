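#' Virtual-interferometer experiment configuration
#'
#' Builds and validates the configuration of a simulated flow-cell
#' interferometry experiment: a calcite surface dissolving at a constant
#' retreat rate next to an inert quartz reference strip, with attached
#' cells that locally slow dissolution and stochastically detach.
#'
#' Units follow instrument conventions: lateral dimensions in micrometres,
#' heights in nanometres, time in hours, retreat rates in micrometres per
#' day (converted internally to nm/h).
#'
#' @param field_width_um,field_height_um Imaged field size (um). The default
#'   400 x 400 um matches a typical VSI region of interest.
#' @param pixel_size_um Lateral sampling (um/pixel); default 0.4.
#' @param frame_interval_min Frame cadence (minutes); default 5.
#' @param duration_h Experiment duration (hours); default 24.
#' @param retreat_rate_um_d True calcite surface retreat rate R (um/day).
#' @param inhibition_factor Under-cell rate factor f in \[0, 1\]: pixels covered
#'   by a cell dissolve at f * R. f = 1 means no protective effect.
#' @param quartz_fraction Fraction of the field width occupied by the static
#'   quartz reference strip (left side of the field).
#' @param n_cells_initial Number of cells seeded on the calcite region.
#' @param n_cells_quartz Number of cells seeded on the quartz strip; these
#'   never detach (used to probe segmentation uncertainty on an inert region).
#' @param cell_diameter_um Mean cell diameter (um); default 4.
#' @param cell_depression_nm Apparent optical depression of a cell body in the
#'   height channel (nm). The true depth is not measurable by VSI; this is a
#'   declared simulation parameter, not a hard-coded constant.
#' @param detachment_mode One of `"none"`, `"uniform_schedule"` (detach times
#'   i.i.d. uniform, giving a linear expected coverage decline) or
#'   `"exponential"` (i.i.d. exponential waiting times).
#' @param detachment_rate_cells_mm2_h Detachment rate d (cells mm^-2 h^-1).
#'   For the uniform schedule the expected count declines at d * A cells/h
#'   over the calcite analysis area A.
#' @param roughness_noise_nm Per-frame i.i.d. Gaussian height noise sd (nm).
#' @param grayscale_background_mean Mean background reflectance, on \[0, 1\].
#' @param grayscale_gradient Peak-to-peak amplitude of a linear illumination
#'   gradient across the field width, on \[0, 1\].
#' @param cell_darkness Grayscale intensity drop inside an attached cell.
#' @param rng_seed Integer seed; all stochastic elements of the generator
#'   (placement, detachment draws, noise) derive from it.
#'
#' @return An object of class `experiment_config` (a validated named list
#'   with derived grid fields `nx`, `ny`, `n_frames`).
#' @examples
#' cfg <- experiment_config(field_width_um = 40, field_height_um = 40,
#'                          duration_h = 1, n_cells_initial = 5)
#' cfg$nx
#' @export
experiment_config <- function(field_width_um = 400,
                              field_height_um = 400,
                              pixel_size_um = 0.4,
                              frame_interval_min = 5,
                              duration_h = 24,
                              retreat_rate_um_d = 10,
                              inhibition_factor = 0.8,
                              quartz_fraction = 0.2,
                              n_cells_initial = 500,
                              n_cells_quartz = 0,
                              cell_diameter_um = 4,
                              cell_depression_nm = 300,
                              detachment_mode = c("uniform_schedule", "none",
                                                  "exponential"),
                              detachment_rate_cells_mm2_h = 163,
                              roughness_noise_nm = 50,
                              grayscale_background_mean = 0.55,
                              grayscale_gradient = 0.10,
                              cell_darkness = 0.30,
                              rng_seed = 1L) {
  detachment_mode <- match.arg(detachment_mode)
  cfg <- list(
    field_width_um = field_width_um,
    field_height_um = field_height_um,
    pixel_size_um = pixel_size_um,
    frame_interval_min = frame_interval_min,
    duration_h = duration_h,
    retreat_rate_um_d = retreat_rate_um_d,
    inhibition_factor = inhibition_factor,
    quartz_fraction = quartz_fraction,
    n_cells_initial = n_cells_initial,
    n_cells_quartz = n_cells_quartz,
    cell_diameter_um = cell_diameter_um,
    cell_depression_nm = cell_depression_nm,
    detachment_mode = detachment_mode,
    detachment_rate_cells_mm2_h = detachment_rate_cells_mm2_h,
    roughness_noise_nm = roughness_noise_nm,
    grayscale_background_mean = grayscale_background_mean,
    grayscale_gradient = grayscale_gradient,
    cell_darkness = cell_darkness,
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "experiment_config"
  validate_config(cfg)
}

#' @keywords internal
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  num_pos <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0
  if (!num_pos(cfg$field_width_um) || !num_pos(cfg$field_height_um))
    stop("field dimensions must be positive")
  if (!num_pos(cfg$pixel_size_um)) stop("pixel_size_um must be positive")

  nx <- cfg$field_width_um / cfg$pixel_size_um
  ny <- cfg$field_height_um / cfg$pixel_size_um
  if (abs(nx - round(nx)) > 1e-6 || abs(ny - round(ny)) > 1e-6)
    stop("field size must be an integer number of pixels ",
         "(field / pixel_size not integral)")
  cfg$nx <- as.integer(round(nx))
  cfg$ny <- as.integer(round(ny))

  nfr <- cfg$duration_h * 60 / cfg$frame_interval_min
  if (abs(nfr - round(nfr)) > 1e-6)
    stop("duration_h must be a whole number of frame intervals")
  cfg$n_frames <- as.integer(round(nfr)) + 1L  # frames at t = 0, dt, ..., T

  if (cfg$inhibition_factor < 0 || cfg$inhibition_factor > 1)
    stop("inhibition_factor must lie in [0, 1]")
  if (cfg$retreat_rate_um_d < 0) stop("retreat_rate_um_d must be >= 0")
  if (cfg$roughness_noise_nm < 0) stop("roughness_noise_nm must be >= 0")
  if (cfg$quartz_fraction < 0 || cfg$quartz_fraction >= 1)
    stop("quartz_fraction must lie in [0, 1)")
  if (cfg$n_cells_initial < 0 || cfg$n_cells_quartz < 0)
    stop("cell counts must be >= 0")
  if (cfg$cell_diameter_um <= 0) stop("cell_diameter_um must be positive")
  if (cfg$detachment_mode != "none" && cfg$detachment_rate_cells_mm2_h <= 0)
    stop("detachment_rate_cells_mm2_h must be > 0 for a detaching mode")
  cfg
}

#' Retreat rate conversion helpers (um/day to nm/h)
#' @keywords internal
um_d_to_nm_h <- function(x) x * 1000 / 24

#' @keywords internal
nm_h_to_um_d <- function(x) x * 24 / 1000

#' Read / write an experiment configuration as YAML
#'
#' @param cfg An `experiment_config`.
#' @param path File path.
#' @return `read_config` returns a validated `experiment_config`;
#'   `write_config` returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "experiment_config"))
  drop <- c("nx", "ny", "n_frames")
  yaml::write_yaml(unclass(cfg)[setdiff(names(cfg), drop)], path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(experiment_config, vals)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Virtual interferometry experiment configuration\n")
  cat(sprintf("  field: %g x %g um (%d x %d px @ %g um/px)\n",
              x$field_width_um, x$field_height_um, x$nx, x$ny,
              x$pixel_size_um))
  cat(sprintf("  frames: %d (every %g min over %g h)\n",
              x$n_frames, x$frame_interval_min, x$duration_h))
  cat(sprintf("  retreat: %g um/d, inhibition factor f = %g\n",
              x$retreat_rate_um_d, x$inhibition_factor))
  cat(sprintf("  cells: %d on calcite, %d on quartz (d = %g um); %s detachment at %g cells/mm2/h\n",
              x$n_cells_initial, x$n_cells_quartz, x$cell_diameter_um,
              x$detachment_mode, x$detachment_rate_cells_mm2_h))
  cat(sprintf("  noise: %g nm; seed %d\n", x$roughness_noise_nm, x$rng_seed))
  invisible(x)
}
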