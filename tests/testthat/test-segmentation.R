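make_disk_mask <- function(n, cx, cy, r) {
  outer(seq_len(n) - 0.5 - cy, seq_len(n) - 0.5 - cx,
        function(a, b) a^2 + b^2 <= r^2)
}

test_that("height-tail thresholding recovers a depressed disk in noise", {
  set.seed(1)
  n <- 200
  disk <- make_disk_mask(n, 100, 100, 12)
  h <- matrix(rnorm(n * n, 0, 10), n, n)
  h[disk] <- h[disk] - 300
  m <- segment_by_height(h)
  expect_gte(jaccard(m, disk), 0.9)
})

test_that("a flat plane yields an empty mask with a warning", {
  h <- matrix(5, 50, 50)
  expect_warning(m <- segment_by_height(h), "degenerate")
  expect_false(any(m))
  # and plain noise with no cells segments (almost) nothing
  set.seed(2)
  hn <- matrix(rnorm(2500, 0, 10), 50, 50)
  lab <- clean_and_label(segment_by_height(hn), pixel_size_um = 0.4)
  expect_identical(nrow(lab$table), 0L)
})

test_that("per-frame height masks track true coverage on a synthetic stack", {
  cfg <- detach_config(inhibition_factor = 1)
  ex <- generate_experiment(cfg)
  for (i in seq_along(ex$stack$frames)) {
    truth_px <- sum(ex$stack$attached[[i]])
    if (truth_px == 0) next
    m <- segment_by_height(ex$stack$frames[[i]]$height,
                           mask = ex$stack$calcite_mask)
    expect_lt(abs(sum(m) - truth_px) / truth_px, 0.1)
  }
})

test_that("adaptive grayscale threshold ignores smooth gradients", {
  n <- 250
  grad <- matrix(rep(seq(0.5, 0.6, length.out = n), each = n), n, n)
  expect_false(any(segment_by_grayscale(grad)))
  # the same image under a global threshold marks a whole flank
  global_mark <- grad < (mean(grad) - 0.02)
  expect_gt(mean(global_mark), 0.01)

  # uniform image: nothing marked
  expect_false(any(segment_by_grayscale(matrix(0.5, 100, 100))))

  # gradient plus 20 dark disks: exactly 20 components after cleanup
  img <- grad
  set.seed(4)
  centers <- expand.grid(x = seq(25, 225, by = 50), y = seq(25, 225, by = 50))
  centers <- centers[1:20, ]
  for (k in seq_len(20))
    img[make_disk_mask(n, centers$x[k], centers$y[k], 5)] <-
      img[make_disk_mask(n, centers$x[k], centers$y[k], 5)] - 0.3
  lab <- clean_and_label(segment_by_grayscale(img), pixel_size_um = 0.4)
  expect_identical(nrow(lab$table), 20L)
})

test_that("grayscale segmentation validates its window", {
  img <- matrix(0.5, 20, 20)
  expect_error(segment_by_grayscale(img, window_px = 4), "odd")
  expect_error(segment_by_grayscale(img, window_px = 21), "larger")
})

test_that("morphological cleanup removes specks and labels 8-connected", {
  # single 1-pixel speck (0.16 um2 at 0.4 um/px) is removed
  m <- matrix(FALSE, 30, 30); m[5, 5] <- TRUE
  expect_identical(nrow(clean_and_label(m, 0.4)$table), 0L)

  # two touching disks merge into one 8-connected component
  m2 <- make_disk_mask(60, 20, 30, 8) | make_disk_mask(60, 36, 30, 8)
  lab2 <- clean_and_label(m2, 0.4)
  expect_identical(nrow(lab2$table), 1L)

  # diagonal contact joins under 8-connectivity (it would split under 4)
  m3 <- matrix(FALSE, 10, 10)
  m3[2:4, 2:4] <- TRUE; m3[5:7, 5:7] <- TRUE
  lab3 <- clean_and_label(m3, 0.4, open = FALSE, min_area_um2 = 0)
  expect_identical(nrow(lab3$table), 1L)

  # 50 disjoint disks stay 50 components, with correct areas in um2
  n <- 400; m4 <- matrix(FALSE, n, n)
  grid <- expand.grid(x = seq(20, 380, by = 51), y = seq(20, 380, by = 51))
  for (k in 1:50) m4 <- m4 | make_disk_mask(n, grid$x[k], grid$y[k], 6)
  lab4 <- clean_and_label(m4, 0.4)
  expect_identical(nrow(lab4$table), 50L)
  expect_equal(sum(lab4$table$area_px) * 0.4^2, sum(lab4$table$area_um2))
})

test_that("segmented area converts to real-valued cell counts", {
  expect_equal(area_to_cell_count(pi * 4, 4), 1.0)
  expect_equal(area_to_cell_count(0, 4), 0)
  expect_equal(area_to_cell_count(1256.6370614, 4), 100, tolerance = 1e-9)
  expect_error(area_to_cell_count(-1, 4), ">= 0")
  expect_error(area_to_cell_count(1, 0), "> 0")
})

test_that("height- and grayscale-derived masks agree on noiseless frames", {
  cfg <- tiny_config(n_cells_initial = 6, inhibition_factor = 1)
  ex <- generate_experiment(cfg)
  for (i in c(1L, length(ex$stack$frames))) {
    fr <- ex$stack$frames[[i]]
    mh <- segment_by_height(fr$height, mask = ex$stack$calcite_mask)
    mg <- segment_by_grayscale(fr$gray) & ex$stack$calcite_mask
    expect_gte(jaccard(mh, mg), 0.8)
  }
})

test_that("count scatter on an inert region sets the detection floor", {
  expect_equal(coverage_uncertainty(rep(100, 10)), 0)
  # alternating +/-8 percent perturbation around the mean reads back ~8%
  counts <- 100 * (1 + 0.08 * rep(c(1, -1), 12))
  expect_equal(coverage_uncertainty(counts), 8, tolerance = 0.03)
  expect_error(coverage_uncertainty(rep(0, 5)), "mean")

  # quartz series from the generator: segmentation noise only, slope
  # statistically indistinguishable from zero
  cfg <- tiny_config(field_width_um = 80, field_height_um = 80,
                     duration_h = 4, frame_interval_min = 30,
                     quartz_fraction = 0.5, n_cells_initial = 3,
                     n_cells_quartz = 6, roughness_noise_nm = 40,
                     retreat_rate_um_d = 2)
  ex <- generate_experiment(cfg)
  cov_q <- coverage_series(ex$stack, method = "height", region = "quartz")
  expect_gt(coverage_uncertainty(cov_q$count), 0)
  fit <- fit_rate(cov_q$count, cov_q$time_h)
  expect_gt(fit$p_value, 0.05)
})
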