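#' Draw a cell detachment schedule
#'
#' Detach times are drawn per cell according to the configured mode.
#' `"uniform_schedule"` draws i.i.d. uniform times on `[0, N0 / (d * A)]`,
#' so the expected attached count declines linearly at `d * A` cells/h
#' (`d` in cells mm^-2 h^-1 over analysis area `A` in mm^2) until the pool
#' is exhausted. `"exponential"` draws i.i.d. exponential waiting times with
#' initial rate matched to `d` (rate per cell = d * A / N0). `"none"` returns
#' `Inf` for every cell. Times beyond the run duration simply mean the cell
#' never detaches within the observed record.
#'
#' @param config An [experiment_config()].
#' @param n_cells Number of cells to schedule (default: `n_cells_initial`).
#' @param area_mm2 Analysis area over which the rate is expressed
#'   (default: the calcite region area implied by the config).
#' @return Numeric vector of detach times (h); `Inf` = never.
#' @export
schedule_detachments <- function(config, n_cells = config$n_cells_initial,
                                 area_mm2 = calcite_area_mm2(config)) {
  stopifnot(inherits(config, "experiment_config"))
  if (n_cells == 0) return(numeric(0))
  mode <- config$detachment_mode
  if (mode == "none") return(rep(Inf, n_cells))
  d <- config$detachment_rate_cells_mm2_h
  if (d <= 0) stop("detachment rate must be > 0 for a detaching mode")
  if (mode == "uniform_schedule") {
    t0 <- n_cells / (d * area_mm2)
    stats::runif(n_cells, 0, t0)
  } else {
    lambda <- d * area_mm2 / n_cells  # per-cell rate (1/h)
    stats::rexp(n_cells, lambda)
  }
}

#' Calcite analysis-region area implied by a configuration (mm^2)
#' @param config An [experiment_config()].
#' @export
calcite_area_mm2 <- function(config) {
  qw <- round(config$quartz_fraction * config$nx)
  (config$nx - qw) * config$ny * (config$pixel_size_um / 1000)^2
}

## ---- internal layout / rendering -------------------------------------------

# Quantization grids: heights to 1 pm (emulating finite instrument record,
# and making disk round-trips exactly lossless), grayscale to 16-bit levels.
snap_pm <- function(z) round(z * 1000) / 1000
snap_gray <- function(g) round(g * 65535) / 65535

# Place n non-overlapping disks with centers uniform over a column band
# [col_min, col_max] (px units, continuous), margin r from band edges and
# field edges. Returns data.frame(x, y) of centers in px units.
place_disks <- function(n, r_px, col_min, col_max, ny, max_attempts = 200L) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  lo_x <- col_min + r_px; hi_x <- col_max - r_px
  lo_y <- r_px; hi_y <- ny - r_px
  if (hi_x <= lo_x || hi_y <= lo_y)
    stop("region too small to place cells of this diameter")
  xs <- numeric(n); ys <- numeric(n); placed <- 0L
  attempts <- 0L; cap <- max_attempts * n
  min_d2 <- (2 * r_px)^2
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > cap)
      stop("cell placement failed: could not place ", n,
           " non-overlapping cells in the region")
    x <- stats::runif(1, lo_x, hi_x); y <- stats::runif(1, lo_y, hi_y)
    if (placed > 0L &&
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) < min_d2)
      next
    placed <- placed + 1L
    xs[placed] <- x; ys[placed] <- y
  }
  data.frame(x = xs, y = ys)
}

# Linear pixel indices (column-major, ny rows) of pixels whose center lies
# inside the disk of radius r_px centered at (x, y) in px units. Pixel (i, j)
# has center (j - 0.5, i - 0.5).
disk_pixels <- function(x, y, r_px, ny, nx) {
  j0 <- max(1L, floor(x - r_px)); j1 <- min(nx, ceiling(x + r_px) + 1L)
  i0 <- max(1L, floor(y - r_px)); i1 <- min(ny, ceiling(y + r_px) + 1L)
  jj <- j0:j1; ii <- i0:i1
  cx <- outer(ii - 0.5 - y, jj - 0.5 - x, function(a, b) a^2 + b^2)
  sel <- which(cx <= r_px^2, arr.ind = TRUE)
  if (nrow(sel) == 0) return(integer(0))
  (jj[sel[, 2]] - 1L) * ny + ii[sel[, 1]]
}

# Build the full experiment layout: masks, placed cells, detachment schedule.
# Consumes RNG (placement + schedule); callers must seed beforehand.
vsi_layout <- function(config, detach_times = NULL) {
  nx <- config$nx; ny <- config$ny
  qw <- as.integer(round(config$quartz_fraction * nx))
  quartz_mask <- matrix(FALSE, ny, nx)
  if (qw > 0) quartz_mask[, seq_len(qw)] <- TRUE
  calcite_mask <- !quartz_mask

  r_px <- (config$cell_diameter_um / 2) / config$pixel_size_um
  cal <- place_disks(config$n_cells_initial, r_px, qw, nx, ny)
  qtz <- place_disks(config$n_cells_quartz, r_px, 0, qw, ny)

  n_cal <- nrow(cal)
  cells <- rbind(cal, qtz)
  cells$on_quartz <- rep(c(FALSE, TRUE), c(n_cal, nrow(qtz)))
  cells$attach_h <- rep(0, nrow(cells))

  if (is.null(detach_times)) {
    detach_cal <- schedule_detachments(config)
  } else {
    stopifnot(length(detach_times) == n_cal)
    detach_cal <- detach_times
  }
  cells$detach_h <- c(detach_cal, rep(Inf, nrow(qtz)))

  pix <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells)))
    pix[[k]] <- disk_pixels(cells$x[k], cells$y[k], r_px, ny, nx)

  list(config = config, nx = nx, ny = ny,
       quartz_mask = quartz_mask, calcite_mask = calcite_mask,
       cells = cells, pix = pix, r_px = r_px,
       rate_nm_h = um_d_to_nm_h(config$retreat_rate_um_d))
}

# Render the height (nm) and grayscale frames at time t (h).
# Consumes one rnorm(n) draw when noise > 0.
render_frame <- function(lay, t) {
  cfg <- lay$config
  n <- lay$nx * lay$ny
  R <- lay$rate_nm_h; f <- cfg$inhibition_factor
  z <- numeric(n)
  z[lay$calcite_mask] <- -R * t

  xfrac <- (rep(seq_len(lay$nx), each = lay$ny) - 0.5) / lay$nx
  g <- cfg$grayscale_background_mean + cfg$grayscale_gradient * (xfrac - 0.5)

  cells <- lay$cells
  for (k in seq_len(nrow(cells))) {
    idx <- lay$pix[[k]]
    if (!length(idx)) next
    if (!cells$on_quartz[k]) {
      tau <- min(cells$detach_h[k], t)
      if (tau > 0) z[idx] <- z[idx] + (1 - f) * R * tau
    }
    if (t < cells$detach_h[k]) {      # still attached: optical artifact
      z[idx] <- z[idx] - cfg$cell_depression_nm
      g[idx] <- g[idx] - cfg$cell_darkness
    }
  }
  if (cfg$roughness_noise_nm > 0)
    z <- z + stats::rnorm(n, 0, cfg$roughness_noise_nm)
  list(height = matrix(snap_pm(z), lay$ny, lay$nx),
       gray = matrix(snap_gray(pmin(pmax(g, 0), 1)), lay$ny, lay$nx))
}

# True (artifact-free, noiseless) height at time t; used for ground truth.
true_height <- function(lay, t) {
  cfg <- lay$config
  R <- lay$rate_nm_h; f <- cfg$inhibition_factor
  z <- numeric(lay$nx * lay$ny)
  z[lay$calcite_mask] <- -R * t
  cells <- lay$cells
  for (k in seq_len(nrow(cells))) {
    if (cells$on_quartz[k]) next
    tau <- min(cells$detach_h[k], t)
    idx <- lay$pix[[k]]
    if (tau > 0 && length(idx)) z[idx] <- z[idx] + (1 - f) * R * tau
  }
  matrix(z, lay$ny, lay$nx)
}

# Iterate over frames, calling fun(frame_index, time_h, height, gray, attached)
# where attached is the logical matrix of currently covered pixels. After the
# last frame, calls cellfree_fun(height) with the noisy cell-free re-imaging
# (post-surfactant analogue: same surface, artifact removed, fresh noise).
stream_experiment <- function(config, fun, cellfree_fun = NULL,
                              detach_times = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$rng_seed)
  lay <- vsi_layout(config, detach_times)
  times <- seq(0, config$duration_h, by = config$frame_interval_min / 60)
  for (i in seq_along(times)) {
    t <- times[i]
    fr <- render_frame(lay, t)
    att <- attached_mask(lay, t)
    fun(i, t, fr$height, fr$gray, att)
  }
  if (!is.null(cellfree_fun)) {
    z <- true_height(lay, config$duration_h)
    if (config$roughness_noise_nm > 0)
      z <- z + stats::rnorm(length(z), 0, config$roughness_noise_nm)
    cellfree_fun(matrix(snap_pm(z), lay$ny, lay$nx))
  }
  invisible(lay)
}

attached_mask <- function(lay, t) {
  m <- matrix(FALSE, lay$ny, lay$nx)
  keep <- lay$cells$detach_h > t
  for (k in which(keep)) m[lay$pix[[k]]] <- TRUE
  m
}

## ---- public generator ------------------------------------------------------

#' Generate a synthetic interferometry experiment with ground truth
#'
#' Simulates the full time-lapse record of a dissolving calcite surface with
#' an inert quartz reference strip and attached cells. Uncovered calcite
#' pixels retreat at the configured rate R; pixels covered by a cell for a
#' cumulative time tau dissolve at f * R while covered, leaving a relief of
#' `(1 - f) * R * tau` once the cell detaches. Attached cells additionally
#' appear as negative height anomalies (the optical artifact of the cell
#' body) and as dark disks in the grayscale channel. The last time point is
#' rendered twice: once as imaged (with attached cells) and once cell-free,
#' emulating ex-situ re-imaging after surfactant removal of the cells.
#'
#' @param config An [experiment_config()].
#' @param frame_subset Optional integer vector of frame indices to retain in
#'   the returned stack (1-based; the random stream is identical whichever
#'   subset is kept). Default: all frames. Use a small subset for long
#'   full-field runs, whose complete stack would be very large in memory.
#' @param detach_times Optional numeric vector overriding the drawn detach
#'   schedule of the calcite cells (h); for controlled experiments.
#' @return A list with elements `stack` (an [image_stack()]) and `truth`
#'   (ground truth: `cells` data frame with 0-based center coordinates,
#'   attach/detach times; `residence_h` map of true per-pixel coverage
#'   duration; `cellfree_height` noiseless final artifact-free map).
#' @examples
#' cfg <- experiment_config(field_width_um = 40, field_height_um = 40,
#'                          duration_h = 2, n_cells_initial = 6,
#'                          roughness_noise_nm = 0)
#' ex <- generate_experiment(cfg)
#' length(ex$stack$frames)
#' @export
generate_experiment <- function(config, frame_subset = NULL,
                                detach_times = NULL) {
  keep <- frame_subset
  frames <- list(); times_kept <- numeric(0)
  cellfree <- NULL
  collect <- function(i, t, height, gray, attached) {
    if (is.null(keep) || i %in% keep) {
      frames[[length(frames) + 1L]] <<- list(height = height, gray = gray,
                                             attached = attached)
      times_kept <<- c(times_kept, t)
    }
  }
  lay <- stream_experiment(config, collect,
                           cellfree_fun = function(z) cellfree <<- z,
                           detach_times = detach_times)

  stack <- image_stack(
    height = lapply(frames, `[[`, "height"),
    grayscale = lapply(frames, `[[`, "gray"),
    times_h = times_kept,
    pixel_size_um = config$pixel_size_um,
    calcite_mask = lay$calcite_mask,
    quartz_mask = lay$quartz_mask,
    cellfree_height = cellfree)
  stack$attached <- lapply(frames, `[[`, "attached")

  truth <- ground_truth(lay)
  list(stack = stack, truth = truth)
}

# Assemble the ground-truth record from a layout.
ground_truth <- function(lay) {
  cfg <- lay$config
  res <- matrix(0, lay$ny, lay$nx)
  cells <- lay$cells
  for (k in seq_len(nrow(cells))) {
    tau <- min(cells$detach_h[k], cfg$duration_h) - cells$attach_h[k]
    idx <- lay$pix[[k]]
    if (length(idx)) res[idx] <- res[idx] + tau
  }
  cellfree <- true_height(lay, cfg$duration_h)
  cells_out <- data.frame(
    id = seq_len(nrow(cells)),
    row = cells$y - 0.5,            # 0-based pixel coordinates of the center
    col = cells$x - 0.5,
    on_quartz = cells$on_quartz,
    attach_h = cells$attach_h,
    detach_h = cells$detach_h,
    n_pixels = vapply(lay$pix, length, integer(1))
  )
  list(cells = cells_out, residence_h = res, cellfree_height = cellfree,
       config = cfg)
}

#' Memory-lean simulation of the quartz-referenced retreat series
#'
#' Streams the synthetic experiment frame by frame (never materializing the
#' stack) and records, per frame, the mean quartz height minus the mean
#' uncovered-calcite height. Currently covered calcite pixels are excluded
#' using the generator's true attachment masks, mirroring the exclusion the
#' analysis applies with segmented masks.
#'
#' @param config An [experiment_config()].
#' @return A data frame with `time_h`, `retreat_nm` (positive = calcite has
#'   retreated below quartz), `n_calcite`, `n_quartz`.
#' @export
simulate_retreat_series <- function(config) {
  out <- vector("list", config$n_frames)
  qw <- as.integer(round(config$quartz_fraction * config$nx))
  qmask <- matrix(FALSE, config$ny, config$nx)
  if (qw > 0) qmask[, seq_len(qw)] <- TRUE
  cmask <- !qmask
  rec <- function(i, t, height, gray, attached) {
    cal <- cmask & !attached
    out[[i]] <<- c(t, mean(height[qmask]) - mean(height[cal]),
                   sum(cal), sum(qmask))
  }
  stream_experiment(config, rec)
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("time_h", "retreat_nm", "n_calcite", "n_quartz")
  df
}

#' Memory-lean simulation of the segmented cell-coverage series
#'
#' Streams the synthetic experiment and segments each grayscale frame with
#' the adaptive local-mean threshold ([segment_by_grayscale()]) followed by
#' morphological cleanup, returning the per-frame dark-area fraction and the
#' area-derived cell count on the calcite analysis region.
#'
#' @param config An [experiment_config()].
#' @param window_px,offset Adaptive threshold parameters
#'   (see [segment_by_grayscale()]).
#' @param min_area_um2 Minimum component area kept (see [clean_and_label()]).
#' @return A data frame with `time_h`, `area_um2`, `fraction`, `count`.
#' @export
simulate_coverage_series <- function(config, window_px = 31, offset = 0.1,
                                     min_area_um2 = NULL) {
  qw <- as.integer(round(config$quartz_fraction * config$nx))
  qmask <- matrix(FALSE, config$ny, config$nx)
  if (qw > 0) qmask[, seq_len(qw)] <- TRUE
  cmask <- !qmask
  out <- vector("list", config$n_frames)
  rec <- function(i, t, height, gray, attached) {
    m <- segment_by_grayscale(gray, window_px = window_px, offset = offset)
    m <- m & cmask
    lab <- clean_and_label(m, pixel_size_um = config$pixel_size_um,
                           min_area_um2 = min_area_um2)
    area <- sum(lab$table$area_um2)
    out[[i]] <<- c(t, area,
                   area / (sum(cmask) * config$pixel_size_um^2),
                   area_to_cell_count(area, config$cell_diameter_um))
  }
  stream_experiment(config, rec)
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("time_h", "area_um2", "fraction", "count")
  df
}
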