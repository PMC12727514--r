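#' In-memory model of a co-registered interferometry time series
#'
#' An `image_stack` holds an ordered series of co-registered frames, each a
#' height map (nm, `NaN` = invalid interferometry pixel) plus a grayscale
#' reflectance image (intensity on \[0, 1\]), together with acquisition times,
#' the lateral pixel size and the calcite / quartz region masks. An optional
#' final cell-free height map (ex-situ re-imaging after cell removal) rides
#' along.
#'
#' @param height List of numeric matrices (nm).
#' @param grayscale List of numeric matrices on \[0, 1\], same shapes.
#' @param times_h Strictly increasing numeric vector of frame times (h).
#' @param pixel_size_um Lateral sampling (um/pixel).
#' @param calcite_mask,quartz_mask Disjoint logical matrices, same shape as
#'   the frames.
#' @param cellfree_height Optional final cell-free height map (nm).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(height, grayscale, times_h, pixel_size_um,
                        calcite_mask, quartz_mask, cellfree_height = NULL) {
  stopifnot(is.list(height), is.list(grayscale),
            length(height) == length(grayscale),
            length(height) == length(times_h))
  if (length(times_h) > 1 && any(diff(times_h) <= 0))
    stop("frame times must be strictly increasing")
  dims <- dim(calcite_mask)
  chk <- function(m, what) {
    if (!identical(dim(m), dims))
      stop(what, " shape does not match the mask raster")
  }
  for (i in seq_along(height)) {
    chk(height[[i]], "height frame"); chk(grayscale[[i]], "grayscale frame")
  }
  chk(quartz_mask, "quartz mask")
  if (!is.null(cellfree_height)) chk(cellfree_height, "cell-free map")
  if (any(calcite_mask & quartz_mask))
    stop("calcite and quartz masks must be disjoint")
  frames <- lapply(seq_along(height), function(i)
    list(height = height[[i]], gray = grayscale[[i]]))
  structure(list(frames = frames, times_h = as.numeric(times_h),
                 pixel_size_um = pixel_size_um,
                 calcite_mask = calcite_mask, quartz_mask = quartz_mask,
                 cellfree_height = cellfree_height),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$calcite_mask)
  cat(sprintf("image_stack: %d frames, %d x %d px @ %g um/px, t = %g..%g h\n",
              length(x$frames), d[1], d[2], x$pixel_size_um,
              min(x$times_h), max(x$times_h)))
  cat(sprintf("  calcite px: %d, quartz px: %d, cell-free map: %s\n",
              sum(x$calcite_mask), sum(x$quartz_mask),
              if (is.null(x$cellfree_height)) "no" else "yes"))
  invisible(x)
}

## ---- TIFF encoding ---------------------------------------------------------

# Heights are written as 32-bit unsigned integer TIFF in picometres above a
# per-file offset recorded in the JSON sidecar; NaN pixels map to a sentinel.
# Values are exactly recoverable because in-memory heights live on the 1 pm
# grid the generator (and reader) uses.
PM_SENTINEL_NA <- 2147483647

encode_height <- function(z, offset_nm) {
  v <- round((z - offset_nm) * 1000)
  v[!is.finite(z)] <- PM_SENTINEL_NA
  if (any(v < 0 | v > PM_SENTINEL_NA, na.rm = TRUE))
    stop("height range exceeds the 32-bit picometre encoding")
  v / (2^32 - 1)
}

decode_height <- function(raw_int, offset_nm) {
  # reassociated so the division matches the generator's picometre grid
  # (k / 1000) bit for bit
  z <- (as.numeric(raw_int) + offset_nm * 1000) / 1000
  z[raw_int == PM_SENTINEL_NA] <- NaN
  dim(z) <- dim(raw_int)
  z
}

#' Write / read an image stack on disk
#'
#' The on-disk layout under `dir` is: `height.tif` (multi-frame 32-bit TIFF,
#' picometre integers above an offset recorded in the sidecar), `grayscale.tif`
#' (multi-frame 16-bit), `masks.tif` (two 8-bit pages: calcite, quartz),
#' `frame_times.csv` (`frame_index`, `time_h`), `stack_meta.json` (units,
#' pixel size, encoding metadata) and optionally `cellfree.tif`. The
#' round-trip `read_stack(write_stack(x))` reproduces height values exactly.
#'
#' @param stack An [image_stack()].
#' @param dir Directory to write to (created if missing).
#' @return `write_stack` returns `dir` invisibly; `read_stack` an
#'   [image_stack()].
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hs <- lapply(stack$frames, `[[`, "height")
  finite_rng <- range(unlist(lapply(hs, function(m) m[is.finite(m)])),
                      if (!is.null(stack$cellfree_height))
                        stack$cellfree_height[is.finite(stack$cellfree_height)])
  offset <- floor(finite_rng[1])
  tiff::writeTIFF(lapply(hs, encode_height, offset_nm = offset),
                  file.path(dir, "height.tif"), bits.per.sample = 32L)
  tiff::writeTIFF(lapply(stack$frames, `[[`, "gray"),
                  file.path(dir, "grayscale.tif"), bits.per.sample = 16L)
  tiff::writeTIFF(list(stack$calcite_mask * 1, stack$quartz_mask * 1),
                  file.path(dir, "masks.tif"), bits.per.sample = 8L)
  if (!is.null(stack$cellfree_height))
    tiff::writeTIFF(encode_height(stack$cellfree_height, offset),
                    file.path(dir, "cellfree.tif"), bits.per.sample = 32L)
  utils::write.csv(
    data.frame(frame_index = seq_along(stack$times_h) - 1L,
               time_h = stack$times_h),
    file.path(dir, "frame_times.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(pixel_size_um = stack$pixel_size_um,
         height_units = "nm", height_encoding = "uint32_pm",
         height_offset_nm = offset, na_sentinel = PM_SENTINEL_NA,
         n_frames = length(stack$frames),
         has_cellfree = !is.null(stack$cellfree_height)),
    file.path(dir, "stack_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "stack_meta.json"),
                              simplifyVector = TRUE)
  times <- utils::read.csv(file.path(dir, "frame_times.csv"))
  h_raw <- tiff::readTIFF(file.path(dir, "height.tif"), all = TRUE,
                          as.is = TRUE)
  g_raw <- tiff::readTIFF(file.path(dir, "grayscale.tif"), all = TRUE,
                          as.is = TRUE)
  if (length(h_raw) != nrow(times))
    stop("frame count (", length(h_raw), ") does not match frame-time rows (",
         nrow(times), ")")
  if (length(g_raw) != length(h_raw))
    stop("height and grayscale frame counts differ")
  m_raw <- tiff::readTIFF(file.path(dir, "masks.tif"), all = TRUE)
  if (length(m_raw) != 2) stop("masks.tif must hold two pages")
  cellfree <- NULL
  if (isTRUE(meta$has_cellfree)) {
    cf <- tiff::readTIFF(file.path(dir, "cellfree.tif"), as.is = TRUE)
    cellfree <- decode_height(cf, meta$height_offset_nm)
  }
  image_stack(
    height = lapply(h_raw, decode_height, offset_nm = meta$height_offset_nm),
    grayscale = lapply(g_raw, function(m) m / 65535),
    times_h = times$time_h,
    pixel_size_um = meta$pixel_size_um,
    calcite_mask = m_raw[[1]] > 0.5,
    quartz_mask = m_raw[[2]] > 0.5,
    cellfree_height = cellfree)
}

#' Write a ground-truth record on disk
#'
#' Writes the cell table as CSV, the true residence-time map as a 32-bit
#' TIFF (hours encoded as milli-hours above zero) plus CSV summary, and the
#' generating configuration as YAML.
#'
#' @param truth The `truth` element of [generate_experiment()] output.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  tiff::writeTIFF(round(truth$residence_h * 1000) / (2^32 - 1),
                  file.path(dir, "truth_residence.tif"),
                  bits.per.sample = 32L)
  tiff::writeTIFF(encode_height(truth$cellfree_height,
                                floor(min(truth$cellfree_height))),
                  file.path(dir, "truth_cellfree.tif"), bits.per.sample = 32L)
  write_config(truth$config, file.path(dir, "config.yaml"))
  invisible(dir)
}
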