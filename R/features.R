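# Spatial-spectral feature extraction: pairwise index heatmaps, principal-
# axis leaf zoning, vein segmentation, moment statistics and GLCM texture.

#' All pairwise index heatmaps of a stack
#'
#' One normalized-difference map per unordered band pair, computed in
#' canonical band order (lower-index band first): `(Ia - Ib) / (Ia + Ib)`.
#' A four-band stack yields exactly choose(4,2) = 6 maps. Off-leaf pixels
#' are marked invalid.
#'
#' @param stack calibrated [band_stack()] (>= 2 bands).
#' @param mask optional [segment_leaf()] result or logical matrix limiting
#'   validity to leaf pixels.
#' @param epsilon denominator floor.
#' @return Named list of [index_map()]s (`"blue_green"`, ...).
#' @export
index_heatmaps <- function(stack, mask = NULL, epsilon = 1e-6) {
  bands <- stack$band_names
  if (length(bands) < 2) stop("index heatmaps require at least 2 bands")
  if (inherits(mask, "leaf_mask")) mask <- mask$mask
  out <- list()
  for (i in seq_len(length(bands) - 1)) {
    for (j in (i + 1):length(bands)) {
      m <- index_map(stack, bands[i], bands[j], epsilon = epsilon)
      if (!is.null(mask)) m$valid <- m$valid & mask
      out[[paste(bands[i], bands[j], sep = "_")]] <- m
    }
  }
  out
}

# Principal-axis frame of a pixel set: returns longitudinal and lateral
# coordinates with a deterministic sign convention (tip - the thin end, with
# the long tail of the longitudinal distribution - at positive u).
.leaf_frame <- function(mask) {
  idx <- which(mask)
  r <- (idx - 1) %% nrow(mask) + 1
  c <- (idx - 1) %/% nrow(mask) + 1
  x <- c - mean(c); y <- r - mean(r)
  mu20 <- mean(x^2); mu02 <- mean(y^2); mu11 <- mean(x * y)
  ang <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  u <- x * cos(ang) + y * sin(ang)
  v <- -x * sin(ang) + y * cos(ang)
  if (mean(u^3) < 0) { u <- -u; v <- -v }
  list(idx = idx, u = u, v = v, angle = ang)
}

# Equal-count binning by rank; deterministic for ties (row-major pixel
# order).
.equal_count_bins <- function(x, n) {
  rk <- rank(x, ties.method = "first")
  pmin(ceiling(rk * n / length(x)), n)
}

#' Partition the leaf into a principal-axis zone grid
#'
#' Transforms leaf pixels into the principal-axis frame (centroid origin,
#' major axis = longitudinal), splits the longitudinal coordinate into
#' `n_longitudinal` equal-count bins and the lateral coordinate into
#' `n_lateral` equal-count bins, and numbers the zones base-to-tip, then
#' side-to-side. The binning is rank-based, so the partition is
#' shape-adaptive and rotation-equivariant.
#'
#' @param mask a [segment_leaf()] result or logical matrix
#'   (single-component).
#' @param n_longitudinal,n_lateral grid dimensions (default 4 x 2).
#' @return A list of class `zone_set` with elements `labels` (integer
#'   matrix, 0 = not leaf, 1..Z), `n_longitudinal`, `n_lateral`.
#' @export
zone_leaf <- function(mask, n_longitudinal = 4, n_lateral = 2) {
  if (inherits(mask, "leaf_mask")) mask <- mask$mask
  stopifnot(is.logical(mask))
  nz <- n_longitudinal * n_lateral
  if (nz > sum(mask)) stop("zone count exceeds leaf area")
  fr <- .leaf_frame(mask)
  bu <- .equal_count_bins(fr$u, n_longitudinal)
  bv <- .equal_count_bins(fr$v, n_lateral)
  labels <- matrix(0L, nrow(mask), ncol(mask))
  labels[fr$idx] <- (bu - 1L) * n_lateral + bv
  structure(list(labels = labels, n_longitudinal = n_longitudinal,
                 n_lateral = n_lateral),
            class = "zone_set")
}

#' Segment leaf veins by edge detection
#'
#' Gradient magnitude of the smoothed green band (the band with the
#' strongest structural contrast of chlorophyll-dense tissue in
#' transmittance), thresholded by hysteresis relative to the in-leaf
#' gradient distribution, followed by morphological closing and an
#' elongation filter that keeps line-like components and discards blobs.
#' Detection is restricted to the leaf interior (a small margin is eroded
#' off so the leaf outline itself is not picked up as an edge).
#'
#' @param stack calibrated [band_stack()].
#' @param mask a [segment_leaf()] result or logical matrix.
#' @param hysteresis_low,hysteresis_high thresholds in sd units above the
#'   mean in-leaf gradient magnitude.
#' @param min_elongation minimum major/minor spread ratio of kept
#'   components.
#' @param sigma Gaussian smoothing sd before the gradient.
#' @param margin_px leaf-boundary margin excluded from detection.
#' @param closing_radius radius of the morphological closing that bridges
#'   the two gradient flanks of each vein across its centerline.
#' @param min_component_px discard components smaller than this.
#' @return A list of class `vein_mask` with element `mask` (subset of the
#'   leaf mask).
#' @export
segment_veins <- function(stack, mask, hysteresis_low = 1, hysteresis_high = 2,
                          min_elongation = 3, sigma = 1, margin_px = 3,
                          closing_radius = 2, min_component_px = 20) {
  if (inherits(mask, "leaf_mask")) mask <- mask$mask
  plane <- get_band(stack, "green")
  sm <- EBImage::gblur(plane, sigma = sigma)
  kx <- matrix(c(-0.5, 0, 0.5), 1, 3)
  gx <- EBImage::filter2(sm, kx, boundary = "replicate")
  gy <- EBImage::filter2(sm, t(kx), boundary = "replicate")
  gmag <- sqrt(gx^2 + gy^2)
  inner <- EBImage::erode(mask + 0,
                          EBImage::makeBrush(2 * margin_px + 1, "disc")) > 0
  g <- gmag[inner]
  if (!length(g))
    return(structure(list(mask = mask & FALSE), class = "vein_mask"))
  lo <- mean(g) + hysteresis_low * sd(g)
  hi <- mean(g) + hysteresis_high * sd(g)
  weak <- gmag >= lo & inner
  strong <- gmag >= hi & inner
  if (!any(strong))
    return(structure(list(mask = mask & FALSE), class = "vein_mask"))
  lab <- EBImage::bwlabel(weak)
  keep_hyst <- unique(lab[strong & lab > 0])
  vm <- matrix(lab %in% keep_hyst, nrow(mask), ncol(mask))
  vm <- EBImage::closing(vm + 0, EBImage::makeBrush(2 * closing_radius + 1,
                                                    "disc")) > 0
  lab2 <- EBImage::bwlabel(vm)
  keep <- .line_like_labels(lab2, min_component_px, min_elongation,
                            max_perp_sd = Inf)
  vm <- matrix(lab2 %in% keep, nrow(mask), ncol(mask)) & mask
  .log_stage("segment_veins", "%.2f%% of leaf", 100 * sum(vm) / sum(mask))
  structure(list(mask = vm), class = "vein_mask")
}

#' Moment statistics of a region
#'
#' Population mean, sd, skewness and excess kurtosis of the plane values
#' inside the region: with `m_k` the k-th central moment (denominator n),
#' skewness = `m3 / m2^1.5` and kurtosis = `m4 / m2^2 - 3`. A constant
#' region has undefined skewness/kurtosis, reported as `NA`.
#'
#' @param plane numeric matrix.
#' @param region logical matrix, nonempty.
#' @return Named list: `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
region_statistics <- function(plane, region) {
  x <- plane[region]
  if (!length(x)) stop("empty region")
  m <- mean(x)
  d <- x - m
  m2 <- mean(d^2); m3 <- mean(d^3); m4 <- mean(d^4)
  if (m2 > 0)
    list(mean = m, sd = sqrt(m2), skewness = m3 / m2^1.5,
         kurtosis = m4 / m2^2 - 3)
  else
    list(mean = m, sd = 0, skewness = NA_real_, kurtosis = NA_real_)
}

#' Haralick GLCM texture features of a region
#'
#' Quantizes the plane to `levels` equal-width bins over the region's
#' [min, max], accumulates symmetric co-occurrence counts over pixel pairs
#' with both endpoints in the region for each offset, normalizes each
#' matrix to sum 1, computes contrast, correlation, energy and homogeneity,
#' and averages the features over offsets. Quantizing over the region range
#' makes the features invariant to affine rescaling of the plane values. A
#' constant region yields contrast 0, energy 1, homogeneity 1 and undefined
#' (`NA`) correlation; a region with no valid pixel pair yields all-`NA`.
#'
#' @param plane numeric matrix.
#' @param region logical matrix, nonempty.
#' @param levels number of gray levels (>= 2).
#' @param offsets list of `c(dr, dc)` pixel offsets.
#' @return Named list: `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_features <- function(plane, region, levels = 16,
                          offsets = list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
  if (levels < 2) stop("levels must be >= 2")
  if (!any(region)) stop("empty region")
  rr <- range(which(rowSums(region) > 0))
  cc <- range(which(colSums(region) > 0))
  p <- plane[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  reg <- region[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  v <- p[reg]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(p), ncol(p))
  if (hi > lo)
    q[reg] <- pmin(floor((p[reg] - lo) / (hi - lo) * levels), levels - 1L) + 1L
  else
    q[reg] <- 1L
  per_offset <- lapply(offsets, function(off) .glcm_offset(q, levels, off))
  ok <- !vapply(per_offset, function(f) all(is.na(unlist(f))), logical(1))
  if (!any(ok))
    return(list(contrast = NA_real_, correlation = NA_real_,
                energy = NA_real_, homogeneity = NA_real_))
  avg <- function(name)
    mean(vapply(per_offset[ok], `[[`, numeric(1), name), na.rm = FALSE)
  list(contrast = avg("contrast"),
       correlation = avg("correlation"),
       energy = avg("energy"),
       homogeneity = avg("homogeneity"))
}

.glcm_offset <- function(q, levels, off) {
  h <- nrow(q); w <- ncol(q)
  dr <- off[1]; dc <- off[2]
  r_lo <- max(1, 1 - dr); r_hi <- min(h, h - dr)
  c_lo <- max(1, 1 - dc); c_hi <- min(w, w - dc)
  if (r_lo > r_hi || c_lo > c_hi)
    return(list(contrast = NA_real_, correlation = NA_real_,
                energy = NA_real_, homogeneity = NA_real_))
  r1 <- r_lo:r_hi
  c1 <- c_lo:c_hi
  A <- q[r1, c1, drop = FALSE]
  B <- q[r1 + dr, c1 + dc, drop = FALSE]
  okp <- !is.na(A) & !is.na(B)
  if (!any(okp))
    return(list(contrast = NA_real_, correlation = NA_real_,
                energy = NA_real_, homogeneity = NA_real_))
  counts <- tabulate((A[okp] - 1L) * levels + B[okp], nbins = levels * levels)
  M <- matrix(counts, levels, levels, byrow = TRUE)
  M <- M + t(M)
  P <- M / sum(M)
  i <- matrix(rep(seq_len(levels), levels), levels)
  j <- t(i)
  pm <- rowSums(P)
  mu <- sum(seq_len(levels) * pm)
  s2 <- sum(seq_len(levels)^2 * pm) - mu^2
  corr <- if (s2 > 0) (sum(P * i * j) - mu^2) / s2 else NA_real_
  list(contrast = sum(P * (i - j)^2),
       correlation = corr,
       energy = sum(P^2),
       homogeneity = sum(P / (1 + abs(i - j))))
}

#' Extract the spatial-spectral feature row of one image
#'
#' For each source plane (the 4 calibrated bands and the 6 pairwise index
#' heatmaps) and each region (whole leaf, every zone, vein, non-vein),
#' computes the 4 moment statistics and the 4 GLCM features; adds the
#' whole-leaf mean NDVI as the named baseline feature. Feature names follow
#' `source__region__stat`. Empty regions yield explicit `NA`s, never silent
#' zeros.
#'
#' @param stack calibrated (reconstructed) [band_stack()].
#' @param mask [segment_leaf()] result.
#' @param zones [zone_leaf()] result.
#' @param veins [segment_veins()] result.
#' @param glcm_levels,glcm_offsets GLCM parameterization.
#' @param epsilon index-map denominator floor.
#' @return One-row `data.frame` of named numeric features.
#' @export
extract_features <- function(stack, mask, zones, veins,
                             glcm_levels = 16,
                             glcm_offsets = list(c(0, 1), c(1, 0),
                                                 c(1, 1), c(1, -1)),
                             epsilon = 1e-6) {
  lmask <- if (inherits(mask, "leaf_mask")) mask$mask else mask
  heat <- index_heatmaps(stack, lmask, epsilon = epsilon)
  planes <- c(
    setNames(lapply(stack$band_names, function(b) get_band(stack, b)),
             stack$band_names),
    setNames(lapply(heat, `[[`, "values"), paste0("idx_", names(heat))))
  regions <- list(leaf = lmask)
  for (z in seq_len(zones$n_longitudinal * zones$n_lateral))
    regions[[paste0("zone", z)]] <- zones$labels == z
  regions$vein <- veins$mask
  regions$nonvein <- lmask & !veins$mask

  vals <- list()
  for (pn in names(planes)) {
    for (rn in names(regions)) {
      reg <- regions[[rn]]
      if (any(reg)) {
        st <- region_statistics(planes[[pn]], reg)
        gl <- glcm_features(planes[[pn]], reg, levels = glcm_levels,
                            offsets = glcm_offsets)
      } else {
        st <- list(mean = NA_real_, sd = NA_real_, skewness = NA_real_,
                   kurtosis = NA_real_)
        gl <- list(contrast = NA_real_, correlation = NA_real_,
                   energy = NA_real_, homogeneity = NA_real_)
      }
      for (s in names(st))
        vals[[paste(pn, rn, s, sep = "__")]] <- st[[s]]
      for (s in names(gl))
        vals[[paste(pn, rn, paste0("glcm_", s), sep = "__")]] <- gl[[s]]
    }
  }
  nd <- ndvi(stack, epsilon = epsilon)
  vals[["ndvi__leaf__mean"]] <- mean(nd$values[lmask])
  as.data.frame(vals, check.names = FALSE)
}

#' @export
print.zone_set <- function(x, ...) {
  counts <- tabulate(x$labels[x$labels > 0],
                     x$n_longitudinal * x$n_lateral)
  cat(sprintf("<zone_set> %d x %d grid over %d leaf px; zone sizes %d-%d\n",
              x$n_longitudinal, x$n_lateral, sum(counts),
              min(counts), max(counts)))
  invisible(x)
}

#' @export
print.vein_mask <- function(x, ...) {
  cat(sprintf("<vein_mask> %d px\n", sum(x$mask)))
  invisible(x)
}
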