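test_that("identity case: no retreat, no cells, no noise gives static frames", {
  cfg <- tiny_config(retreat_rate_um_d = 0, inhibition_factor = 1,
                     n_cells_initial = 0)
  ex <- generate_experiment(cfg)
  h1 <- ex$stack$frames[[1]]$height
  for (fr in ex$stack$frames) expect_identical(fr$height, h1)
  rs <- retreat_series(ex$stack)
  expect_equal(rs$retreat_nm, rep(0, nrow(rs)))
})

test_that("noiseless retreat follows the closed form z(t) = z0 - R t", {
  cfg <- tiny_config(retreat_rate_um_d = 10.3, n_cells_initial = 0,
                     duration_h = 24, frame_interval_min = 120)
  ex <- generate_experiment(cfg)
  rs <- retreat_series(ex$stack)
  # quartz minus calcite after 24 h at 10.3 um/d: 10300 nm, to within the
  # 1 pm recording grid of the height channel
  expect_lt(abs(rs$retreat_nm[nrow(rs)] - 10300), 1e-3)
  expect_lt(max(abs(rs$retreat_nm - 10300 / 24 * rs$time_h)), 1e-3)
})

test_that("under-cell inhibition leaves the expected topographic relief", {
  # a cell resident 4.0 h of a 24 h run at 10.3 um/d with f = 0.8 leaves
  # (1 - f) R tau = 0.2 * 10.3 * 4/24 = 0.343 um of relief
  cfg <- tiny_config(field_width_um = 20, field_height_um = 20,
                     duration_h = 24, frame_interval_min = 120,
                     retreat_rate_um_d = 10.3, n_cells_initial = 1)
  ex <- generate_experiment(cfg, frame_subset = 1L, detach_times = 4.0)
  cf <- ex$stack$cellfree_height
  covered <- ex$truth$residence_h > 0
  bg <- ex$stack$calcite_mask & !covered
  relief_um <- (mean(cf[covered]) - mean(cf[bg])) / 1000
  expect_equal(relief_um, 0.2 * 10.3 * 4 / 24, tolerance = 1e-5)
})

test_that("quartz pixels are bit-identical across frames without noise", {
  cfg <- tiny_config(n_cells_initial = 4, n_cells_quartz = 2)
  ex <- generate_experiment(cfg)
  q <- ex$stack$quartz_mask & !ex$stack$attached[[1]]
  ref <- ex$stack$frames[[1]]$height[q]
  for (fr in ex$stack$frames) expect_identical(fr$height[q], ref)
})

test_that("apparent height is true height minus the optical depression", {
  cfg <- tiny_config(n_cells_initial = 5, cell_depression_nm = 250)
  ex <- generate_experiment(cfg)
  t_final <- cfg$duration_h
  R <- cfg$retreat_rate_um_d * 1000 / 24
  covered <- ex$stack$attached[[length(ex$stack$frames)]] &
    ex$stack$calcite_mask
  apparent <- ex$stack$frames[[length(ex$stack$frames)]]$height[covered]
  true_z <- -R * t_final + (1 - cfg$inhibition_factor) * R * t_final
  expect_equal(apparent, rep(true_z - 250, sum(covered)), tolerance = 1e-6)
})

test_that("true residence map totals match per-cell pixel bookkeeping", {
  cfg <- detach_config(roughness_noise_nm = 0)
  ex <- generate_experiment(cfg, frame_subset = 1L)
  cells <- ex$truth$cells
  tau <- pmin(cells$detach_h, cfg$duration_h) - cells$attach_h
  expect_equal(sum(ex$truth$residence_h), sum(cells$n_pixels * tau))
  expect_true(all(ex$truth$residence_h <= cfg$duration_h + 1e-12))
  expect_true(all(cells$detach_h >= cells$attach_h))
})

test_that("with f = 1 final topography is independent of residence time", {
  cfg <- experiment_config(field_width_um = 140, field_height_um = 140,
                           pixel_size_um = 0.4, duration_h = 12,
                           frame_interval_min = 60, retreat_rate_um_d = 10,
                           inhibition_factor = 1, quartz_fraction = 0.2,
                           n_cells_initial = 60, roughness_noise_nm = 40,
                           detachment_rate_cells_mm2_h = 60 / (12 * 0.8 * 0.0196),
                           rng_seed = 5L)
  ex <- generate_experiment(cfg, frame_subset = cfg$n_frames)
  r <- correlate_residence_topography(ex$truth$residence_h,
                                      ex$stack$cellfree_height,
                                      mask = ex$stack$calcite_mask)
  expect_lt(abs(r$r), 0.05)
})

test_that("cell placement fails loudly when the region cannot hold the cells", {
  expect_error(generate_experiment(
    tiny_config(field_width_um = 20, field_height_um = 20,
                n_cells_initial = 50)),
    "placement|too small")
})

test_that("uniform detachment schedule reproduces the target decline slope", {
  # N0 = 500 cells over A = 0.16 mm2 at d = 1298 cells/mm2/h: expected
  # count slope is -d * A = -207.7 cells/h; average over replicate draws
  cfg <- experiment_config(quartz_fraction = 0, n_cells_initial = 500,
                           detachment_rate_cells_mm2_h = 1298,
                           duration_h = 3)
  A <- calcite_area_mm2(cfg)
  expect_equal(A, 0.16, tolerance = 1e-12)
  t0 <- 500 / (1298 * A)
  times <- seq(0, t0, by = 5 / 60)
  slopes <- vapply(1:24, function(s) {
    set.seed(s)
    detach <- schedule_detachments(cfg)
    counts <- vapply(times, function(t) sum(detach > t), numeric(1))
    fit_rate(counts, times)$slope
  }, numeric(1))
  expect_equal(mean(slopes), -1298 * A, tolerance = 0.1)
})

test_that("exponential detachment waiting times have the configured mean", {
  cfg <- experiment_config(detachment_mode = "exponential",
                           detachment_rate_cells_mm2_h = 1298,
                           quartz_fraction = 0, n_cells_initial = 500)
  A <- calcite_area_mm2(cfg)
  n <- 10000
  lambda <- 1298 * A / n  # per-cell rate when n cells share the pool
  set.seed(42)
  draws <- schedule_detachments(cfg, n_cells = n)
  expect_equal(mean(draws), 1 / lambda,
               tolerance = 3 / sqrt(n))  # 3 sd of the mean, relative scale
})

test_that("detachment mode none keeps coverage constant", {
  cfg <- tiny_config(n_cells_initial = 5)
  ex <- generate_experiment(cfg)
  counts <- vapply(ex$stack$attached, sum, numeric(1))
  expect_true(all(counts == counts[1]))
  expect_true(all(ex$truth$cells$detach_h == Inf))
})

test_that("streaming and materialized generation agree", {
  cfg <- tiny_config(roughness_noise_nm = 15, n_cells_initial = 5)
  ex <- generate_experiment(cfg)
  rs_stream <- simulate_retreat_series(cfg)
  rs_stack <- retreat_series(ex$stack, cell_masks = ex$stack$attached)
  expect_equal(rs_stream$retreat_nm, rs_stack$retreat_nm)
})
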