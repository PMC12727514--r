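#' Quartz-referenced surface retreat series
#'
#' For each frame, the mean quartz height minus the mean calcite height
#' (nm): as the calcite dissolves, the difference grows at the surface
#' retreat rate. Calcite pixels currently covered by a cell can be excluded
#' (their apparent height carries the optical cell artifact); pass the
#' per-frame cell masks from segmentation or the generator.
#'
#' @param stack An [image_stack()] with non-empty calcite and quartz masks.
#' @param cell_masks Optional list of logical matrices (one per frame):
#'   currently covered pixels, excluded from the calcite mean.
#' @return Data frame with `time_h`, `retreat_nm`, `n_calcite`, `n_quartz`
#'   (counts of valid pixels used).
#' @export
retreat_series <- function(stack, cell_masks = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  if (!any(stack$calcite_mask) || !any(stack$quartz_mask))
    stop("both calcite and quartz masks must be non-empty")
  if (length(stack$frames) < 3) stop("need at least 3 frames")
  if (!is.null(cell_masks))
    stopifnot(length(cell_masks) == length(stack$frames))
  out <- lapply(seq_along(stack$frames), function(i) {
    h <- stack$frames[[i]]$height
    cal <- stack$calcite_mask
    if (!is.null(cell_masks)) cal <- cal & !cell_masks[[i]]
    hq <- h[stack$quartz_mask]; hc <- h[cal]
    hq <- hq[is.finite(hq)]; hc <- hc[is.finite(hc)]
    if (!length(hq) || !length(hc)) stop("no valid pixels in a region")
    c(time_h = stack$times_h[i], retreat_nm = mean(hq) - mean(hc),
      n_calcite = length(hc), n_quartz = length(hq))
  })
  as.data.frame(do.call(rbind, out))
}

#' Ordinary least-squares rate fit of a scalar time series
#'
#' Fits `values ~ times` by OLS; the slope is the rate in input units per
#' hour. Used both for retreat series (nm/h, convertible to um/day) and for
#' coverage series (cells/h, normalized by area to cells mm^-2 h^-1).
#'
#' @param values Numeric response series.
#' @param times_h Numeric times (h), same length, not all equal.
#' @return An object of class `rate_fit`: `slope`, `intercept`, `se`
#'   (slope standard error), `r_squared`, `n`, `p_value` (slope t-test).
#' @examples
#' f <- fit_rate(2 * (0:10), 0:10)
#' f$slope  # 2
#' @export
fit_rate <- function(values, times_h) {
  stopifnot(length(values) == length(times_h))
  if (length(values) < 3) stop("need at least 3 points")
  if (stats::sd(times_h) == 0) stop("singular design: all times equal")
  fit <- stats::lm(values ~ times_h)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(slope = unname(co["times_h", "Estimate"]),
                 intercept = unname(co["(Intercept)", "Estimate"]),
                 se = unname(co["times_h", "Std. Error"]),
                 r_squared = sm$r.squared,
                 n = length(values),
                 p_value = unname(co["times_h", "Pr(>|t|)"])),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("rate_fit: slope %.4g +/- %.3g per h (R2 %.4f, n %d, p %.3g)\n",
              x$slope, x$se, x$r_squared, x$n, x$p_value))
  invisible(x)
}

#' Fit the calcite retreat rate from a retreat series
#'
#' @param series Data frame from [retreat_series()] (or any with `time_h`
#'   and `retreat_nm`).
#' @return A `rate_fit` with extra fields `rate_um_d` and `se_um_d`.
#' @export
fit_retreat_rate <- function(series) {
  f <- fit_rate(series$retreat_nm, series$time_h)
  f$rate_um_d <- nm_h_to_um_d(f$slope)
  f$se_um_d <- nm_h_to_um_d(f$se)
  f
}

#' Fit the cell detachment rate from a coverage series
#'
#' Fits the declining portion of the attached-cell count by OLS and
#' normalizes the slope by the analysis area, giving cells mm^-2 h^-1
#' (reported positive for a decline). Frames after the population is
#' exhausted (count below `tail_frac` of the initial count) are excluded:
#' with a finite cell pool the expected count is linear only until the last
#' cell leaves.
#'
#' @param counts Per-frame cell counts.
#' @param times_h Frame times (h).
#' @param area_mm2 Analysis-region area (mm^2).
#' @param tail_frac Fraction of the initial count below which trailing
#'   frames are dropped (default 0.02).
#' @return A `rate_fit` with extra fields `rate_cells_mm2_h` and
#'   `se_cells_mm2_h`.
#' @export
fit_detachment_rate <- function(counts, times_h, area_mm2,
                                tail_frac = 0.02) {
  stopifnot(length(counts) == length(times_h), area_mm2 > 0)
  floor_count <- tail_frac * counts[1]
  live <- which(counts > floor_count)
  last <- if (length(live)) min(max(live) + 1L, length(counts)) else
    length(counts)
  use <- seq_len(last)
  f <- fit_rate(counts[use], times_h[use])
  f$rate_cells_mm2_h <- -f$slope / area_mm2
  f$se_cells_mm2_h <- f$se / area_mm2
  f
}

#' Arithmetic mean roughness Ra of a height map window
#'
#' `Ra = mean(|z_i - mean(z)|)` over the valid pixels of a square window
#' (or the whole map), in nm.
#'
#' @param height Numeric height matrix (nm); `NaN` ignored.
#' @param pixel_size_um Lateral pixel size (um).
#' @param origin_um Optional `c(x, y)` of the window's top-left corner (um,
#'   from the top-left of the map). `NULL`: whole map.
#' @param size_um Window edge length (um); required with `origin_um`.
#' @return An object of class `roughness_result`: `Ra_nm`, `mean_z_nm`,
#'   `n`, `origin_um`, `size_um`.
#' @export
roughness_Ra <- function(height, pixel_size_um, origin_um = NULL,
                         size_um = NULL) {
  if (!is.null(origin_um)) {
    stopifnot(!is.null(size_um))
    j0 <- floor(origin_um[1] / pixel_size_um) + 1L
    i0 <- floor(origin_um[2] / pixel_size_um) + 1L
    w <- round(size_um / pixel_size_um)
    if (i0 < 1 || j0 < 1 || i0 + w - 1L > nrow(height) ||
        j0 + w - 1L > ncol(height))
      stop("window extends beyond the raster")
    height <- height[i0:(i0 + w - 1L), j0:(j0 + w - 1L)]
  }
  v <- height[is.finite(height)]
  if (length(v) < 2) stop("need at least 2 valid pixels")
  zbar <- mean(v)
  structure(list(Ra_nm = mean(abs(v - zbar)), mean_z_nm = zbar,
                 n = length(v), origin_um = origin_um, size_um = size_um),
            class = "roughness_result")
}

#' @export
print.roughness_result <- function(x, ...) {
  cat(sprintf("Ra = %.3g nm (mean z %.4g nm, n = %d)\n",
              x$Ra_nm, x$mean_z_nm, x$n))
  invisible(x)
}

#' Sub-window roughness report
#'
#' Places `n_windows` square sub-windows at seeded-random positions fully
#' inside the analysis region and reports Ra per window plus the
#' across-window mean and standard deviation (the "mean +/- sd" summary
#' style used for spatial-heterogeneity estimates).
#'
#' @param height Height map (nm).
#' @param pixel_size_um Lateral pixel size (um).
#' @param region_mask Logical matrix; windows must lie entirely inside.
#' @param n_windows Number of windows (default 3).
#' @param size_um Window edge (um, default 30).
#' @param seed Integer seed making placement deterministic.
#' @return List with `windows` (list of `roughness_result`), `Ra_mean_nm`,
#'   `Ra_sd_nm`, `origins_um` (matrix of window origins).
#' @export
subwindow_report <- function(height, pixel_size_um, region_mask,
                             n_windows = 3, size_um = 30, seed = 1L) {
  w <- round(size_um / pixel_size_um)
  ny <- nrow(height); nx <- ncol(height)
  if (w > ny || w > nx) stop("window larger than the raster")
  set.seed(seed)
  origins <- matrix(NA_real_, n_windows, 2)
  results <- vector("list", n_windows)
  for (k in seq_len(n_windows)) {
    ok <- FALSE
    for (a in seq_len(1000)) {
      i0 <- sample.int(ny - w + 1L, 1L)
      j0 <- sample.int(nx - w + 1L, 1L)
      if (all(region_mask[i0:(i0 + w - 1L), j0:(j0 + w - 1L)])) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place a ", size_um,
                  " um window inside the region")
    origins[k, ] <- c((j0 - 1L) * pixel_size_um, (i0 - 1L) * pixel_size_um)
    results[[k]] <- roughness_Ra(height, pixel_size_um,
                                 origin_um = origins[k, ], size_um = size_um)
  }
  ra <- vapply(results, `[[`, numeric(1), "Ra_nm")
  list(windows = results, Ra_mean_nm = mean(ra), Ra_sd_nm = stats::sd(ra),
       origins_um = origins)
}

#' Convert a surface retreat rate to a molar dissolution flux
#'
#' `flux = retreat * 1e-6 / (86400 * Vm * 1e-6)` with the retreat in um/day
#' and the molar volume Vm in cm^3/mol (36.93 for calcite), giving
#' mol m^-2 s^-1. `molar_flux_to_retreat` is the exact inverse.
#'
#' @param retreat_um_d Surface retreat rate (um/day), >= 0.
#' @param molar_volume_cm3_mol Molar volume (cm^3/mol), > 0.
#' @return Dissolution flux (mol m^-2 s^-1).
#' @examples
#' retreat_to_molar_flux(2.7)  # ~8.5e-7 mol m-2 s-1
#' @export
retreat_to_molar_flux <- function(retreat_um_d, molar_volume_cm3_mol = 36.93) {
  if (any(retreat_um_d < 0)) stop("retreat must be >= 0")
  if (molar_volume_cm3_mol <= 0) stop("molar volume must be positive")
  retreat_um_d * 1e-6 / (86400 * molar_volume_cm3_mol * 1e-6)
}

#' @rdname retreat_to_molar_flux
#' @param flux_mol_m2_s Dissolution flux (mol m^-2 s^-1).
#' @export
molar_flux_to_retreat <- function(flux_mol_m2_s,
                                  molar_volume_cm3_mol = 36.93) {
  if (molar_volume_cm3_mol <= 0) stop("molar volume must be positive")
  flux_mol_m2_s * 86400 * molar_volume_cm3_mol * 1e-6 / 1e-6
}
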