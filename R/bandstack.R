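#' @importFrom stats rnorm runif sd median quantile setNames t.test p.adjust predict var
#' @importFrom utils read.csv write.csv
NULL

# Canonical band order: visible bands by ascending wavelength, NIR last.
.canonical_bands <- c("blue", "green", "red", "nir")
.canonical_wavelengths <- c(blue = 460, green = 525, red = 630, nir = 850)

# Power-of-two scale used to place float pixel values inside the [0,1]
# range that 32-bit TIFF pages are stored on (the storage grid is fixed
# point, so precision is .float_tiff_scale / 2^32, about 2.4e-7).
.float_tiff_scale <- 1024

#' Four-band image stack
#'
#' The central raster container of the pipeline: a `height x width x n_bands`
#' array of nonnegative pixel values plus per-band metadata. Raw stacks hold
#' sensor counts in `[0, bit_depth_max]`; calibrated stacks hold transmittance
#' ratios and may exceed 1.
#'
#' @param pixels numeric array of shape (height, width, n_bands).
#' @param band_names character vector of band labels; subset of
#'   blue/green/red/nir, unique.
#' @param wavelengths_nm numeric vector of band peak wavelengths (nm).
#' @param bit_depth_max saturation value of the source encoding
#'   (255 for 8-bit sensors; 1 for calibrated stacks).
#' @return An object of class `band_stack`.
#' @export
band_stack <- function(pixels,
                       band_names = .canonical_bands,
                       wavelengths_nm = unname(.canonical_wavelengths[band_names]),
                       bit_depth_max = 255) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  nb <- dim(pixels)[3]
  if (nb != length(band_names) || nb != length(wavelengths_nm))
    stop("band metadata length does not match number of planes")
  if (anyDuplicated(band_names))
    stop("band names must be unique")
  if (!all(band_names %in% .canonical_bands))
    stop("unknown band label(s): ",
         paste(setdiff(band_names, .canonical_bands), collapse = ", "))
  if (!all(is.finite(pixels)))
    stop("pixel values must be finite")
  if (min(pixels) < 0)
    stop("pixel values must be nonnegative")
  if (!is.numeric(bit_depth_max) || bit_depth_max <= 0)
    stop("bit_depth_max must be positive")
  structure(
    list(pixels = pixels,
         band_names = as.character(band_names),
         wavelengths_nm = as.numeric(wavelengths_nm),
         bit_depth_max = bit_depth_max),
    class = "band_stack")
}

#' @export
dim.band_stack <- function(x) dim(x$pixels)

#' @export
print.band_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<band_stack> %d x %d px, %d band(s): %s\n", d[1], d[2], d[3],
              paste(sprintf("%s(%gnm)", x$band_names, x$wavelengths_nm),
                    collapse = " ")))
  cat(sprintf("  bit_depth_max = %g, range [%.4g, %.4g]\n",
              x$bit_depth_max, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Extract one band plane as a matrix
#'
#' @param stack a [band_stack()].
#' @param band band label ("blue", "green", "red" or "nir").
#' @return Numeric matrix (height x width).
#' @export
get_band <- function(stack, band) {
  stopifnot(inherits(stack, "band_stack"))
  i <- match(band, stack$band_names)
  if (is.na(i)) stop("band '", band, "' not present in stack")
  stack$pixels[, , i]
}

#' Number of bands in a stack
#' @param stack a [band_stack()].
#' @export
n_bands <- function(stack) dim(stack$pixels)[3]

#' Read a multispectral TIFF stack
#'
#' Reads either a multipage TIFF (one page per band) or four sibling
#' single-page TIFFs with `_blue/_green/_red/_nir` suffixes. Bands are
#' returned in canonical order (blue, green, red, nir) regardless of on-disk
#' order; the on-disk order is declared through `band_order`, never inferred
#' from pixel statistics. Integer pages are read bit-exactly; 32-bit float
#' pages are descaled by the package's fixed power-of-two storage scale.
#'
#' @param path TIFF path (for `per_band_files`, the basename without the band
#'   suffix, e.g. `"img.tif"` for `img_blue.tif` etc.).
#' @param layout `"multipage"` or `"per_band_files"`.
#' @param band_order on-disk band order (declared mapping).
#' @param bit_depth_max override for the saturation value; by default 2^bits-1
#'   for integer pages and 255 for float pages (8-bit camera default).
#' @return A [band_stack()] in canonical band order.
#' @export
read_stack <- function(path, layout = c("multipage", "per_band_files"),
                       band_order = .canonical_bands, bit_depth_max = NULL) {
  layout <- match.arg(layout)
  if (!all(band_order %in% .canonical_bands))
    stop("unknown band label(s) in band_order: ",
         paste(setdiff(band_order, .canonical_bands), collapse = ", "))
  if (layout == "multipage") {
    if (!file.exists(path)) stop("no such file: ", path)
    meta <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
    if (nrow(meta) != length(band_order))
      stop(sprintf("expected %d pages, found %d", length(band_order), nrow(meta)))
    bits <- meta$bits.per.sample[1]
    planes <- .read_tiff_pages(path, bits)
  } else {
    base <- sub("\\.tiff?$", "", path)
    files <- paste0(base, "_", band_order, ".tif")
    missing <- !file.exists(files)
    if (any(missing))
      stop("missing band file(s): ", paste(files[missing], collapse = ", "))
    planes <- list(); bits <- NULL
    for (i in seq_along(files)) {
      m <- tiff::readTIFF(files[i], payload = FALSE, all = TRUE)
      if (is.null(bits)) bits <- m$bits.per.sample[1]
      p <- .read_tiff_pages(files[i], m$bits.per.sample[1])
      planes[[i]] <- p[[1]]
    }
  }
  d1 <- dim(planes[[1]])
  for (i in seq_along(planes)) {
    if (!identical(dim(planes[[i]]), d1))
      stop(sprintf("band '%s' has dimensions %dx%d, expected %dx%d",
                   band_order[i], dim(planes[[i]])[1], dim(planes[[i]])[2],
                   d1[1], d1[2]))
  }
  if (is.null(bit_depth_max))
    bit_depth_max <- if (bits %in% c(8L, 16L)) 2^bits - 1 else 255
  # permute declared on-disk order into canonical order
  keep <- .canonical_bands[.canonical_bands %in% band_order]
  px <- array(0, dim = c(d1, length(keep)))
  for (i in seq_along(keep))
    px[, , i] <- planes[[match(keep[i], band_order)]]
  band_stack(px, band_names = keep, bit_depth_max = bit_depth_max)
}

.read_tiff_pages <- function(path, bits) {
  if (bits %in% c(8L, 16L)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    lapply(pages, function(p) { storage.mode(p) <- "double"; p })
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    lapply(pages, function(p) p * .float_tiff_scale)
  }
}

#' Write a multispectral stack as a multipage TIFF
#'
#' Integer-valued stacks with `bit_depth_max` 255 or 65535 are written as
#' 8/16-bit pages and round-trip bit-exactly through [read_stack()]. All
#' other stacks are written as 32-bit pages holding `value / 1024` (the
#' storage grid is fixed point on \[0, 1\], so values are rounded once to an
#' absolute precision of about 2.4e-7 and are stable under further round
#' trips). Values must lie below 1024.
#'
#' @param stack a valid [band_stack()]; non-finite pixels are rejected.
#' @param path output path.
#' @param compression TIFF compression, `"none"` (default) or `"deflate"`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, compression = "none") {
  stopifnot(inherits(stack, "band_stack"))
  px <- stack$pixels
  if (!all(is.finite(px))) stop("stack contains non-finite pixel values")
  bdm <- stack$bit_depth_max
  integral <- bdm %in% c(255, 65535) && max(px) <= bdm &&
    isTRUE(all(px == round(px)))
  if (integral) {
    bits <- if (bdm == 255) 8L else 16L
    pages <- lapply(seq_len(dim(px)[3]), function(i) px[, , i] / bdm)
  } else {
    if (max(px) >= .float_tiff_scale)
      stop("pixel values exceed the float storage range")
    bits <- 32L
    # the 32-bit TIFF path truncates to a fixed-point grid on write and
    # rescales differently on read; pre-biasing each value to the middle of
    # its grid cell makes the stored level exactly round(x * 2^32) and the
    # round trip stable
    pages <- lapply(seq_len(dim(px)[3]), function(i) {
      k <- pmin(round(px[, , i] / .float_tiff_scale * 2^32), 2^32 - 2)
      (k + 0.5) / (2^32 - 1)
    })
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = compression)
  invisible(path)
}

#' Write / read a boolean mask as a single-page 0/255 TIFF
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path` invisibly for the writer; logical matrix for the reader.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  tiff::writeTIFF(ifelse(mask, 1, 0), path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  m > 0
}

#' Default nitrogen-treatment label set
#'
#' Treatments are expressed as percentages of the farmer's normal nitrogen
#' rate (FNR).
#' @export
default_treatments <- function() c("0%", "40%", "60%", "80%", "100%", "120%")

#' Load a sample manifest
#'
#' The manifest is a CSV with header
#' `image_path,white_id,treatment,plot,plant` mapping each raw image to its
#' white-reference session and treatment label.
#'
#' @param path CSV path.
#' @param treatments allowed treatment label set.
#' @return A `data.frame` of class `sample_manifest`.
#' @export
load_manifest <- function(path, treatments = default_treatments()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop("cannot parse manifest: ",
                                          conditionMessage(e)))
  required <- c("image_path", "white_id", "treatment", "plot", "plant")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$treatment), treatments)
  if (length(bad))
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(treatments, collapse = ", "))
  df$treatment <- factor(df$treatment, levels = treatments)
  attr(df, "treatments") <- treatments
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Pipeline configuration defaults, optionally overridden from YAML
#'
#' Holds band mapping, segmentation/detection thresholds and seeds used by
#' the command-line interface. Any subset of fields may be overridden by the
#' YAML file; unknown fields are rejected.
#'
#' @param path optional YAML file.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- list(
    band_order = .canonical_bands,
    bit_depth_max = 255,
    calibration_epsilon = 1e-6,
    ndvi_threshold = 0.1,
    min_object_px = 500,
    gabor_orientations = c(75, 90, 105),
    gabor_wavelength_px = 4,
    response_k = 3,
    dilation_radius_px = 2,
    zones = c(4, 2),
    glcm_levels = 16,
    seed = 1)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  cfg
}

# Stage logging, gated by options(leafmsi.verbose = TRUE).
.log_stage <- function(stage, ...) {
  if (isTRUE(getOption("leafmsi.verbose", FALSE)))
    message(sprintf("[leafmsi:%s] %s", stage, sprintf(...)))
  invisible(NULL)
}
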