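# Small, fast configurations reused across tests.

# Noiseless miniature field with a handful of persistent cells.
tiny_config <- function(...) {
  defaults <- list(field_width_um = 60, field_height_um = 60,
                   pixel_size_um = 0.4, duration_h = 2,
                   frame_interval_min = 30, retreat_rate_um_d = 10,
                   inhibition_factor = 0.8, quartz_fraction = 0.25,
                   n_cells_initial = 6, roughness_noise_nm = 0,
                   detachment_mode = "none", rng_seed = 1L)
  args <- utils::modifyList(defaults, list(...))
  do.call(experiment_config, args)
}

# A detaching-population scenario sized for quick segmentation runs.
detach_config <- function(...) {
  defaults <- list(field_width_um = 120, field_height_um = 120,
                   pixel_size_um = 0.4, duration_h = 4,
                   frame_interval_min = 20, retreat_rate_um_d = 5,
                   inhibition_factor = 1, quartz_fraction = 0,
                   n_cells_initial = 40, roughness_noise_nm = 10,
                   detachment_mode = "uniform_schedule",
                   # pool exhausted right at the end of the run
                   detachment_rate_cells_mm2_h = 40 / (4 * 0.0144),
                   rng_seed = 3L)
  args <- utils::modifyList(defaults, list(...))
  do.call(experiment_config, args)
}

# Height matrices for closed-form roughness fixtures.
tilted_plane <- function(n, slope_per_px) {
  matrix(rep(slope_per_px * (seq_len(n) - 0.5), each = n), n, n)
}
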