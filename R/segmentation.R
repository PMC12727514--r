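#' Segment attached cells from the height-depression artifact
#'
#' Attached cells reflect light from the cell body and register as shallow
#' negative height anomalies relative to the surrounding surface. This
#' detector thresholds the lower tail of the height histogram: a pixel is
#' marked covered when its height lies more than a threshold depth below the
#' robust background mode. The depth defaults to `k_mad` times the MAD of
#' the heights; an absolute cutoff (nm) can be given instead.
#'
#' @param height Numeric height matrix (nm); `NaN` pixels are ignored.
#' @param mask Optional logical matrix restricting the analysis region
#'   (e.g. the calcite mask). Pixels outside are never marked.
#' @param k_mad Threshold depth in MAD units below the mode (default 5).
#' @param depth_nm Optional absolute threshold depth (nm); overrides `k_mad`.
#' @return Logical matrix of covered pixels. A degenerate (constant)
#'   histogram yields an empty mask with a warning.
#' @export
segment_by_height <- function(height, mask = NULL, k_mad = 5,
                              depth_nm = NULL) {
  v <- if (is.null(mask)) height else ifelse(mask, height, NaN)
  n_region <- if (is.null(mask)) length(height) else sum(mask)
  vals <- v[is.finite(v)]
  if (length(vals) < 2) stop("too few valid pixels to segment")
  if (length(vals) < 0.5 * n_region)
    stop("more than half of the region is invalid (NaN)")
  bg <- height_mode(vals)
  depth <- if (!is.null(depth_nm)) depth_nm else k_mad * stats::mad(vals)
  if (depth <= 0) {
    # noiseless data: the MAD of a mostly-flat surface is 0; fall back to
    # half the depth of the lower tail so clean depressions still segment
    depth <- (bg - min(vals)) / 2
  }
  if (depth <= 0) {
    warning("degenerate height histogram: zero spread, returning empty mask")
    return(matrix(FALSE, nrow(height), ncol(height)))
  }
  out <- is.finite(v) & (v < bg - depth)
  out[is.na(out)] <- FALSE
  out
}

# Robust background level: mode of a kernel density estimate over a sample
# of the finite heights (the histogram peak tracks the uncovered surface as
# long as coverage is a minority of pixels).
height_mode <- function(vals) {
  if (length(vals) > 2e5) vals <- vals[seq(1, length(vals), length.out = 2e5)]
  if (stats::mad(vals) == 0) return(stats::median(vals))
  d <- stats::density(vals, n = 512)
  d$x[which.max(d$y)]
}

#' Segment attached cells by adaptive grayscale thresholding
#'
#' Cells appear darker than the surrounding mineral background. A local
#' threshold is computed for each pixel from the mean intensity of its
#' square neighborhood (exact box mean via an integral image with
#' edge-replicated padding); a pixel is marked when its intensity falls more
#' than `offset` below that local mean. The local reference makes the
#' detector robust to smooth illumination gradients that defeat a global
#' threshold.
#'
#' @param image Numeric intensity matrix on \[0, 1\].
#' @param window_px Odd neighborhood width in pixels (>= 3; default 31,
#'   comfortably larger than a cell footprint).
#' @param offset Intensity drop below the local mean required to mark a
#'   pixel (default 0.1).
#' @return Logical matrix of marked (dark) pixels.
#' @export
segment_by_grayscale <- function(image, window_px = 31, offset = 0.1) {
  if (window_px < 3 || window_px %% 2 == 0)
    stop("window_px must be odd and >= 3")
  if (window_px > min(dim(image)))
    stop("window larger than the image")
  image < local_mean(image, window_px) - offset
}

# Exact box mean with edge replication, via a padded integral image.
local_mean <- function(x, w) {
  r <- (w - 1L) / 2L
  nr <- nrow(x); nc <- ncol(x)
  xp <- x[c(rep(1L, r), seq_len(nr), rep(nr, r)),
          c(rep(1L, r), seq_len(nc), rep(nc, r)), drop = FALSE]
  s <- apply(apply(xp, 2L, cumsum), 1L, cumsum)  # transposed cumulative sum
  s <- t(s)
  s <- rbind(0, cbind(0, s))
  i1 <- seq_len(nr); j1 <- seq_len(nc)
  (s[i1 + w, j1 + w, drop = FALSE] - s[i1, j1 + w, drop = FALSE] -
     s[i1 + w, j1, drop = FALSE] + s[i1, j1, drop = FALSE]) / (w * w)
}

#' Morphological cleanup and connected-component labeling
#'
#' Applies a binary opening with a 3x3 box structuring element, removes
#' components smaller than `min_area_um2`, and labels the surviving
#' components under 8-connectivity.
#'
#' @param mask Logical matrix.
#' @param pixel_size_um Lateral pixel size (um), used to express areas in
#'   um^2.
#' @param min_area_um2 Minimum component area kept. Default: a quarter of
#'   the footprint of one cell of diameter `cell_diameter_um`.
#' @param cell_diameter_um Mean cell diameter (um) used for the default
#'   minimum area; default 4.
#' @param open Logical; apply the opening (default `TRUE`).
#' @return A list with `labels` (integer matrix, 0 = background), `mask`
#'   (cleaned logical matrix) and `table` (data frame: `id`, `area_px`,
#'   `area_um2`, `centroid_row`, `centroid_col`).
#' @export
clean_and_label <- function(mask, pixel_size_um, min_area_um2 = NULL,
                            cell_diameter_um = 4, open = TRUE) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- mask > 0
  if (is.null(min_area_um2))
    min_area_um2 <- 0.25 * pi * (cell_diameter_um / 2)^2
  if (open && any(mask)) {
    m <- EBImage::opening(mask * 1, EBImage::makeBrush(3, shape = "box"))
    mask <- as.matrix(m) > 0.5
  }
  lab <- label_components_8(mask)
  if (max(lab) == 0)
    return(list(labels = lab, mask = mask, table = empty_component_table()))
  area_px <- tabulate(lab[lab > 0L])
  keep <- which(area_px * pixel_size_um^2 >= min_area_um2)
  relab <- integer(length(area_px))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  mask <- lab > 0L
  if (!length(keep))
    return(list(labels = lab, mask = mask, table = empty_component_table()))
  idx <- which(lab > 0L)
  ids <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  tab <- data.frame(
    id = seq_along(keep),
    area_px = as.integer(tabulate(ids, nbins = length(keep))),
    centroid_row = as.numeric(tapply(rows, ids, mean)),
    centroid_col = as.numeric(tapply(cols, ids, mean)))
  tab$area_um2 <- tab$area_px * pixel_size_um^2
  tab <- tab[c("id", "area_px", "area_um2", "centroid_row", "centroid_col")]
  list(labels = lab, mask = mask, table = tab)
}

empty_component_table <- function() {
  data.frame(id = integer(0), area_px = integer(0), area_um2 = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0))
}

# 8-connected component labeling on the foreground pixel graph.
label_components_8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (!length(idx)) return(lab)
  ny <- nrow(mask); nx <- ncol(mask)
  id <- integer(ny * nx)
  id[idx] <- seq_along(idx)
  rows <- (idx - 1L) %% ny + 1L
  cols <- (idx - 1L) %/% ny + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nr <- rows + off[1]; nc <- cols + off[2]
    ok <- nr >= 1L & nr <= ny & nc >= 1L & nc <= nx
    nidx <- (nc[ok] - 1L) * ny + nr[ok]
    hit <- mask[nidx]
    edges[[length(edges) + 1L]] <-
      rbind(id[idx[ok][hit]], id[nidx[hit]])
  }
  el <- do.call(cbind, edges)
  if (length(el)) {
    g <- igraph::make_graph(as.vector(el), n = length(idx), directed = FALSE)
    memb <- igraph::components(g)$membership
  } else {
    memb <- seq_along(idx)
  }
  # deterministic labels in raster order of first occurrence
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  lab[idx] <- relab[memb]
  lab
}

#' Convert a segmented dark area to an equivalent cell count
#'
#' The cumulative segmented area is divided by the footprint of one cell of
#' the given mean diameter, `pi * (d / 2)^2`, yielding a real-valued count.
#'
#' @param total_area_um2 Total segmented area (um^2); must be >= 0.
#' @param mean_diameter_um Mean cell diameter (um); default 4.
#' @return Real-valued equivalent cell count.
#' @examples
#' area_to_cell_count(pi * 4, 4)  # exactly one cell
#' @export
area_to_cell_count <- function(total_area_um2, mean_diameter_um = 4) {
  if (any(total_area_um2 < 0)) stop("area must be >= 0")
  if (mean_diameter_um <= 0) stop("diameter must be > 0")
  total_area_um2 / (pi * (mean_diameter_um / 2)^2)
}

#' Per-frame cell coverage series of a materialized stack
#'
#' Segments every frame with either the grayscale adaptive threshold (the
#' channel used for coverage and detachment series) or the height-tail
#' detector, cleans and labels the masks, and converts areas to counts.
#'
#' @param stack An [image_stack()].
#' @param method `"grayscale"` or `"height"`.
#' @param cell_diameter_um Mean cell diameter for the count conversion.
#' @param ... Passed to the segmenter ([segment_by_grayscale()] or
#'   [segment_by_height()]).
#' @param region One of `"calcite"` (default) or `"quartz"`: analysis region.
#' @return A data frame with `time_h`, `area_um2`, `fraction`, `count` and
#'   attribute `"masks"` holding the cleaned per-frame masks.
#' @export
coverage_series <- function(stack, method = c("grayscale", "height"),
                            cell_diameter_um = 4, region = "calcite", ...) {
  method <- match.arg(method)
  rmask <- if (region == "calcite") stack$calcite_mask else stack$quartz_mask
  a_px <- sum(rmask)
  masks <- vector("list", length(stack$frames))
  out <- lapply(seq_along(stack$frames), function(i) {
    fr <- stack$frames[[i]]
    m <- if (method == "grayscale")
      segment_by_grayscale(fr$gray, ...)
    else
      segment_by_height(fr$height, mask = rmask, ...)
    m <- m & rmask
    lab <- clean_and_label(m, pixel_size_um = stack$pixel_size_um,
                           cell_diameter_um = cell_diameter_um)
    masks[[i]] <<- lab$mask
    area <- sum(lab$table$area_um2)
    c(time_h = stack$times_h[i], area_um2 = area,
      fraction = area / (a_px * stack$pixel_size_um^2),
      count = area_to_cell_count(area, cell_diameter_um))
  })
  df <- as.data.frame(do.call(rbind, out))
  attr(df, "masks") <- masks
  df
}

#' Relative scatter of a cell-count series on an inert region
#'
#' On a region with no true detachment (the quartz reference), frame-to-frame
#' variation of the estimated count reflects segmentation / processing
#' uncertainty alone. Returned as `sd(counts) / mean(counts) * 100` (percent),
#' the detection floor below which a fitted detachment slope is not
#' meaningful.
#'
#' @param counts Numeric vector of per-frame counts (>= 3 values).
#' @return Relative standard deviation in percent.
#' @export
coverage_uncertainty <- function(counts) {
  if (length(counts) < 3) stop("need at least 3 frames")
  m <- mean(counts)
  if (m == 0) stop("mean count is zero; uncertainty undefined")
  stats::sd(counts) / m * 100
}

#' Jaccard index of two binary masks
#' @param a,b Logical matrices of equal shape.
#' @return Intersection over union; 1 when both masks are empty.
#' @export
jaccard <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
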