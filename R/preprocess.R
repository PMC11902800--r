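# Flat-field calibration and guard-thread reconstruction.

#' Flat-field calibration against a white reference
#'
#' Divides each band of the raw stack by its white-reference band
#' (`calibrated = raw / max(white, epsilon)`), removing the LED illumination
#' nonuniformity. Each band has its own white reference plane. Pixels where
#' the white reference falls below `epsilon` are unreliable and flagged in a
#' companion validity mask (attribute `"valid"`).
#'
#' @param raw raw [band_stack()].
#' @param white white-reference [band_stack()] of identical shape and band
#'   order.
#' @param epsilon small positive floor for the denominator, in white-stack
#'   units.
#' @return A calibrated [band_stack()] (transmittance scale,
#'   `bit_depth_max = 1`) with a logical `"valid"` attribute.
#' @export
calibrate <- function(raw, white, epsilon = 1e-6) {
  stopifnot(inherits(raw, "band_stack"), inherits(white, "band_stack"))
  if (!identical(dim(raw$pixels), dim(white$pixels)))
    stop("raw and white stacks have different shapes")
  if (!identical(raw$band_names, white$band_names))
    stop("raw and white stacks have different band order")
  if (epsilon <= 0) stop("epsilon must be positive")
  cal <- raw$pixels / pmax(white$pixels, epsilon)
  valid <- rowSums(white$pixels < epsilon, dims = 2) == 0
  out <- band_stack(cal, band_names = raw$band_names,
                    wavelengths_nm = raw$wavelengths_nm, bit_depth_max = 1)
  attr(out, "valid") <- valid
  .log_stage("calibrate", "%d x %d x %d, %.3f%% pixels flagged",
             dim(cal)[1], dim(cal)[2], dim(cal)[3], 100 * mean(!valid))
  out
}

#' Even-symmetric 2-D Gabor kernel
#'
#' A DC-free cosine-phase Gabor elongated along the line direction it is
#' tuned to; responds strongly to thin dark/bright lines of width about half
#' the carrier wavelength and weakly to smooth gradients.
#'
#' @param wavelength_px carrier wavelength in pixels.
#' @param orientation_deg direction of the line the kernel detects, degrees
#'   (0 = horizontal line, 90 = vertical line).
#' @param sigma Gaussian envelope sd across the line (default 0.56 x
#'   wavelength).
#' @param gamma spatial aspect ratio; the envelope extends `sigma / gamma`
#'   along the line.
#' @return Numeric matrix (odd-sized).
#' @export
gabor_kernel <- function(wavelength_px, orientation_deg,
                         sigma = 0.56 * wavelength_px, gamma = 0.33) {
  half <- ceiling(2.5 * sigma / gamma)
  xs <- seq(-half, half)
  X <- matrix(rep(xs, each = length(xs)), length(xs))  # column offset
  Y <- matrix(xs, length(xs), length(xs))              # row offset
  th <- orientation_deg * pi / 180
  # coordinates: along the line / perpendicular to it
  along <- X * cos(th) - Y * sin(th)
  perp <- X * sin(th) + Y * cos(th)
  g <- exp(-(perp^2 + gamma^2 * along^2) / (2 * sigma^2)) *
    cos(2 * pi * perp / wavelength_px)
  g - mean(g)
}

#' Detect guard threads with an oriented Gabor bank
#'
#' Runs on a single detection plane, the band-mean of the log-transmittance
#' (occlusion is multiplicative, so on a log scale the threads have the same
#' contrast over leaf and background). For each orientation the even-Gabor
#' response is computed with dark-line polarity (threads are occlusions, so
#' they are always darker than their surround; using the signed response
#' instead of its magnitude keeps the filter's sidelobes from widening the
#' detection halo). Pixels whose max-over-orientation response exceeds
#' `mean + response_k * sd` are flagged, the flagged set is dilated, and only
#' line-like connected components (elongated and straight) are retained -
#' curved leaf margins and blob artifacts are discarded.
#'
#' @param stack calibrated [band_stack()].
#' @param gabor_orientations line orientations (degrees) of the filter bank.
#' @param gabor_wavelength_px Gabor carrier wavelength, about twice the
#'   expected thread width.
#' @param response_k threshold in sd units above the mean response.
#' @param gabor_sigma Gaussian envelope sd of the Gabor bank (default
#'   0.45 x wavelength, tuned to thin-line detection).
#' @param dilation_radius_px dilation radius applied to the flagged set.
#' @param min_component_px discard components smaller than this.
#' @param min_elongation minimum major/minor spread ratio of a kept
#'   component.
#' @param max_perp_sd maximum perpendicular spread (pixel sd about the
#'   component's principal axis) of a kept component; enforces straightness.
#' @param mask_cap error if the final mask covers more than this fraction.
#' @return A list of class `thread_mask` with elements `mask` (logical
#'   matrix) and `per_band` (FALSE: detection ran on one plane).
#' @export
detect_threads <- function(stack,
                           gabor_orientations = c(75, 90, 105),
                           gabor_wavelength_px = 4,
                           gabor_sigma = 0.45 * gabor_wavelength_px,
                           response_k = 3,
                           dilation_radius_px = 2,
                           min_component_px = 50,
                           min_elongation = 5,
                           max_perp_sd = 4,
                           mask_cap = 0.2) {
  stopifnot(inherits(stack, "band_stack"))
  plane <- rowSums(log(pmax(stack$pixels, 1e-3)), dims = 2) / dim(stack$pixels)[3]
  h <- nrow(plane); w <- ncol(plane)
  resp <- matrix(-Inf, h, w)
  # circular boundary: the log-calibrated background is ~0 at the frame
  # borders, so wrap-around introduces no spurious structure, and the FFT
  # path stays at the native frame size
  for (o in gabor_orientations) {
    k <- gabor_kernel(gabor_wavelength_px, o, sigma = gabor_sigma)
    r <- -EBImage::filter2(plane, k, boundary = "circular")  # dark lines
    resp <- pmax(resp, r)
  }
  thr <- mean(resp) + response_k * sd(resp)
  flag <- resp > thr
  if (!any(flag))
    return(structure(list(mask = flag, per_band = FALSE), class = "thread_mask"))
  if (dilation_radius_px > 0)
    flag <- EBImage::dilate(flag + 0,
                            EBImage::makeBrush(2 * dilation_radius_px + 1,
                                               "disc")) > 0
  lab <- EBImage::bwlabel(flag)
  keep <- .line_like_labels(lab, min_component_px, min_elongation, max_perp_sd)
  mask <- matrix(lab %in% keep, h, w)
  frac <- mean(mask)
  if (frac > mask_cap)
    stop(sprintf("thread mask covers %.1f%% of the frame (cap %.0f%%); check detection parameters",
                 100 * frac, 100 * mask_cap))
  .log_stage("detect_threads", "%d component(s), %.2f%% of frame",
             length(keep), 100 * frac)
  structure(list(mask = mask, per_band = FALSE), class = "thread_mask")
}

# Second-moment screening of labelled components: keep elongated, straight
# ones. Returns the retained label ids.
.line_like_labels <- function(lab, min_px, min_elong, max_perp_sd) {
  idx <- which(lab > 0)
  if (!length(idx)) return(integer(0))
  l <- lab[idx]
  r <- (idx - 1) %% nrow(lab) + 1
  c <- (idx - 1) %/% nrow(lab) + 1
  n <- tabulate(l)
  sr <- rowsum(r, l); sc <- rowsum(c, l)
  srr <- rowsum(r * r, l); scc <- rowsum(c * c, l); src <- rowsum(r * c, l)
  ids <- as.integer(rownames(sr))
  nn <- n[ids]
  mr <- sr[, 1] / nn; mc <- sc[, 1] / nn
  vrr <- srr[, 1] / nn - mr^2
  vcc <- scc[, 1] / nn - mc^2
  vrc <- src[, 1] / nn - mr * mc
  tr2 <- (vrr + vcc) / 2
  det_ <- vrr * vcc - vrc^2
  disc <- pmax(tr2^2 - det_, 0)
  l1 <- tr2 + sqrt(disc)  # variance along principal axis
  l2 <- pmax(tr2 - sqrt(disc), 0)
  elong <- sqrt(l1 / pmax(l2, 1e-9))
  perp_sd <- sqrt(l2)
  ids[nn >= min_px & elong >= min_elong & perp_sd <= max_perp_sd]
}

#' Fill masked pixels by harmonic (diffusion) interpolation
#'
#' Replaces each masked pixel, per band, by the solution of the discrete
#' Laplace equation with Dirichlet boundary values taken from the
#' surrounding unmasked ring (4-neighbour stencil; at the frame border the
#' missing neighbours are simply dropped). The sparse symmetric
#' positive-definite system is solved exactly by Cholesky factorization, so
#' the result is deterministic, satisfies the discrete maximum principle per
#' connected component, and reproduces affine intensity fields exactly in
#' the interior. Unmasked pixels are returned bit-identical.
#'
#' @param stack a [band_stack()].
#' @param mask a `thread_mask` or logical matrix of the same shape.
#' @return The reconstructed [band_stack()].
#' @export
inpaint <- function(stack, mask) {
  stopifnot(inherits(stack, "band_stack"))
  if (inherits(mask, "thread_mask")) mask <- mask$mask
  stopifnot(is.logical(mask))
  d <- dim(stack$pixels)
  if (!identical(dim(mask), d[1:2]))
    stop("mask shape does not match stack")
  if (!any(mask)) return(stack)
  h <- d[1]; w <- d[2]; nb <- d[3]
  idx <- which(mask)
  nunk <- length(idx)
  unk <- integer(h * w); unk[idx] <- seq_len(nunk)
  r <- (idx - 1) %% h + 1
  c <- (idx - 1) %/% h + 1

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_n <- numeric(nunk)
  B <- matrix(0, nunk, nb)
  px <- stack$pixels
  has_boundary <- logical(nunk)
  for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    rn <- r + s[1]; cn <- c + s[2]
    ok <- rn >= 1 & rn <= h & cn >= 1 & cn <= w
    nidx <- (cn[ok] - 1) * h + rn[ok]
    who <- which(ok)
    diag_n[who] <- diag_n[who] + 1
    nu <- unk[nidx]
    interior <- nu > 0
    ii <- c(ii, who[interior]); jj <- c(jj, nu[interior])
    xx <- c(xx, rep(-1, sum(interior)))
    bnd <- who[!interior]
    if (length(bnd)) {
      has_boundary[bnd] <- TRUE
      for (b in seq_len(nb))
        B[bnd, b] <- B[bnd, b] + px[nidx[!interior] + (b - 1) * h * w]
    }
  }
  # every connected masked component must reach some unmasked pixel
  lab <- EBImage::bwlabel(mask)
  comp <- lab[idx]
  if (!all(seq_len(max(comp)) %in% unique(comp[has_boundary])))
    stop("inpainting region has no boundary data")

  A <- Matrix::sparseMatrix(i = c(ii, seq_len(nunk)),
                            j = c(jj, seq_len(nunk)),
                            x = c(xx, diag_n),
                            dims = c(nunk, nunk))
  sol <- Matrix::solve(A, B)
  out <- px
  for (b in seq_len(nb))
    out[idx + (b - 1) * h * w] <- as.numeric(sol[, b])
  .log_stage("inpaint", "%d masked px filled in %d band(s)", nunk, nb)
  band_stack(pmax(out, 0), band_names = stack$band_names,
             wavelengths_nm = stack$wavelengths_nm,
             bit_depth_max = stack$bit_depth_max)
}

#' @export
print.thread_mask <- function(x, ...) {
  cat(sprintf("<thread_mask> %d px (%.2f%% of %d x %d frame)\n", sum(x$mask),
              100 * mean(x$mask), nrow(x$mask), ncol(x$mask)))
  invisible(x)
}
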