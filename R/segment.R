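# NDVI computation and leaf isolation.
#
# In the transmittance regime the background (backlight, no leaf) is bright
# in every band, so its NDVI is ~0 (NIR ~ R), while leaf tissue absorbs red
# strongly and transmits NIR, giving clearly positive NDVI. A positive
# threshold plus morphology therefore separates leaf from background.

#' Normalized-difference index map for a band pair
#'
#' Computes `(Ia - Ib) / (Ia + Ib)` per pixel for an ordered band pair.
#' Pixels whose denominator falls below `epsilon` are set to 0 and marked
#' invalid. Values are bounded in [-1, 1] for nonnegative stacks and
#' invariant to simultaneous positive scaling of both bands.
#'
#' @param stack a [band_stack()] containing both bands.
#' @param band_a,band_b band labels (numerator is `a - b`).
#' @param epsilon denominator floor.
#' @return A list of class `index_map` with elements `values` (matrix),
#'   `band_pair`, `valid` (logical matrix).
#' @export
index_map <- function(stack, band_a, band_b, epsilon = 1e-6) {
  A <- get_band(stack, band_a)
  B <- get_band(stack, band_b)
  den <- A + B
  valid <- den >= epsilon
  vals <- matrix(0, nrow(A), ncol(A))
  vals[valid] <- (A[valid] - B[valid]) / den[valid]
  structure(list(values = vals, band_pair = c(band_a, band_b), valid = valid),
            class = "index_map")
}

#' NDVI map
#'
#' Normalized Difference Vegetation Index, `(NIR - R) / (NIR + R)`: the
#' (nir, red) special case of [index_map()].
#'
#' @inheritParams index_map
#' @export
ndvi <- function(stack, epsilon = 1e-6) {
  if (!all(c("nir", "red") %in% stack$band_names))
    stop("NDVI requires 'red' and 'nir' bands")
  index_map(stack, "nir", "red", epsilon = epsilon)
}

#' Segment the leaf from the bright transmittance background
#'
#' Thresholds the NDVI map, applies morphological closing and hole filling,
#' discards small objects and keeps the largest connected component. The
#' component's area, centroid and principal-axis angle (from second
#' moments) are recorded.
#'
#' @param ndvi_map an [ndvi()] / [index_map()] result.
#' @param threshold NDVI threshold; pixels above it are foreground.
#' @param min_object_px discard components smaller than this.
#' @param closing_radius radius of the morphological closing brush.
#' @return A list of class `leaf_mask` with elements `mask`, `area_px`,
#'   `centroid` (row, col), `major_axis_angle` (radians).
#' @export
segment_leaf <- function(ndvi_map, threshold = 0.1, min_object_px = 500,
                         closing_radius = 3) {
  stopifnot(inherits(ndvi_map, "index_map"))
  fg <- ndvi_map$values > threshold
  if (!any(fg)) stop("no leaf found")
  if (closing_radius > 0)
    fg <- EBImage::closing(fg + 0,
                           EBImage::makeBrush(2 * closing_radius + 1,
                                              "disc")) > 0
  fg <- EBImage::fillHull(fg + 0) > 0
  lab <- EBImage::bwlabel(fg)
  sizes <- tabulate(lab[lab > 0])
  sizes[sizes < min_object_px] <- 0
  if (!any(sizes > 0)) stop("no leaf found")
  mask <- lab == which.max(sizes)
  idx <- which(mask)
  r <- (idx - 1) %% nrow(mask) + 1
  c <- (idx - 1) %/% nrow(mask) + 1
  mr <- mean(r); mc <- mean(c)
  mu20 <- mean((c - mc)^2)   # x = column
  mu02 <- mean((r - mr)^2)
  mu11 <- mean((c - mc) * (r - mr))
  angle <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  .log_stage("segment_leaf", "area %d px, centroid (%.1f, %.1f), angle %.3f rad",
             length(idx), mr, mc, angle)
  structure(list(mask = mask, area_px = length(idx),
                 centroid = c(row = mr, col = mc),
                 major_axis_angle = angle),
            class = "leaf_mask")
}

#' @export
print.index_map <- function(x, ...) {
  cat(sprintf("<index_map> (%s - %s)/(%s + %s), %d x %d px, %.1f%% valid\n",
              x$band_pair[1], x$band_pair[2], x$band_pair[1], x$band_pair[2],
              nrow(x$values), ncol(x$values), 100 * mean(x$valid)))
  cat(sprintf("  value range [%.3f, %.3f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.leaf_mask <- function(x, ...) {
  cat(sprintf("<leaf_mask> %d px (%.1f%% of %d x %d frame)\n", x$area_px,
              100 * x$area_px / length(x$mask), nrow(x$mask), ncol(x$mask)))
  cat(sprintf("  centroid (%.1f, %.1f), major axis %.1f deg\n",
              x$centroid[1], x$centroid[2], x$major_axis_angle * 180 / pi))
  invisible(x)
}
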