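# Synthetic backlit transmittance leaf scenes with ground truth.
#
# The generator emulates the imaging regime of the device: a single flattened
# corn leaf lit from below, so the background (no leaf) is bright and the
# leaf appears as a transmittance silhouette; five thin nylon guard threads
# cross the frame; LED illumination is smoothly nonuniform per band.
# Transmittance follows Beer-Lambert: T_b = exp(-absorbance_b * chlorophyll),
# which is monotone in chlorophyll and yields closed-form oracles for
# calibration and NDVI.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Synthetic scene configuration
#'
#' Bundles every knob of the synthetic leaf-scene generator. Defaults encode
#' the imaging conditions the pipeline targets: a 1200 x 1920 px frame
#' (the camera's resolution), five straight non-crossing near-vertical guard
#' threads of 2 px width, order-2 polynomial LED illumination fields
#' normalized to mean 1, Beer-Lambert band absorbances ordered
#' red > blue > green >> NIR (chlorophyll absorbs red, transmits NIR), an
#' exposure factor leaving sensor headroom, and Gaussian sensor noise of 1%
#' of full scale. Treatment effects give, per nitrogen treatment, the mean
#' chlorophyll scale, the base-to-tip gradient slope and the within-class
#' log-scale standard deviation.
#'
#' @param image_shape (height, width) in pixels.
#' @param n_threads number of guard threads (default 5).
#' @param thread_width_px thread width in pixels.
#' @param treatments treatment label set.
#' @param treatment_effects named list (one entry per treatment) of lists
#'   with fields `mean`, `slope`, `sd`.
#' @param absorbance_coeffs per-band Beer-Lambert absorbance per unit
#'   chlorophyll; red must exceed NIR.
#' @param noise_sd Gaussian sensor noise sd as a fraction of `bit_depth_max`.
#' @param illumination_order polynomial order of the illumination surface.
#' @param occlusion_factor multiplicative attenuation of thread pixels.
#' @param exposure global exposure factor (headroom against clipping).
#' @param vein_factor chlorophyll multiplier on vein pixels (< 1: veins are
#'   less chlorophyll-dense, so brighter in transmittance).
#' @param texture_amp amplitude of the smooth low-frequency chlorophyll
#'   texture (relative).
#' @param n_secondary_veins secondary veins per side of the midrib.
#' @param vein_width_px,midrib_width_px vein widths in pixels.
#' @param bit_depth_max sensor saturation value.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(image_shape = c(1200, 1920),
                         n_threads = 5,
                         thread_width_px = 2,
                         treatments = default_treatments(),
                         treatment_effects = NULL,
                         absorbance_coeffs = c(blue = 1.6, green = 0.8,
                                               red = 2.0, nir = 0.05),
                         noise_sd = 0.01,
                         illumination_order = 2,
                         occlusion_factor = 0.1,
                         exposure = 0.7,
                         vein_factor = 0.5,
                         texture_amp = 0.08,
                         n_secondary_veins = 4,
                         vein_width_px = 3,
                         midrib_width_px = 5,
                         bit_depth_max = 255) {
  if (is.null(treatment_effects)) {
    # Strong, well-separated treatment means; chlorophyll rises with N rate
    # up to 100% FNR and drops under over-fertilization (120%). Nitrogen
    # deficiency shows as a steeper base-to-tip decline.
    stopifnot(identical(treatments, default_treatments()))
    treatment_effects <- list(
      "0%"   = list(mean = 0.30, slope = 0.55, sd = 0.025),
      "40%"  = list(mean = 0.70, slope = 0.45, sd = 0.025),
      "60%"  = list(mean = 0.90, slope = 0.35, sd = 0.025),
      "80%"  = list(mean = 1.10, slope = 0.28, sd = 0.025),
      "100%" = list(mean = 1.35, slope = 0.20, sd = 0.025),
      "120%" = list(mean = 1.20, slope = 0.25, sd = 0.025))
  }
  if (!setequal(names(treatment_effects), treatments))
    stop("treatment_effects keys must equal the treatment label set")
  if (n_threads < 0) stop("n_threads must be >= 0")
  if (absorbance_coeffs[["red"]] <= absorbance_coeffs[["nir"]])
    stop("red absorbance must exceed NIR absorbance")
  structure(
    list(image_shape = as.integer(image_shape),
         n_threads = as.integer(n_threads),
         thread_width_px = thread_width_px,
         treatments = treatments,
         treatment_effects = treatment_effects,
         absorbance_coeffs = absorbance_coeffs,
         noise_sd = noise_sd,
         illumination_order = illumination_order,
         occlusion_factor = occlusion_factor,
         exposure = exposure,
         vein_factor = vein_factor,
         texture_amp = texture_amp,
         n_secondary_veins = as.integer(n_secondary_veins),
         vein_width_px = vein_width_px,
         midrib_width_px = midrib_width_px,
         bit_depth_max = bit_depth_max),
    class = "synth_config")
}

#' Scenario configuration: overlapping treatment means
#'
#' Emulates the field situation where only the unfertilized treatment is
#' separable by whole-leaf mean NDVI: the 0% class has a far lower mean
#' chlorophyll scale, while the remaining five classes share the same mean
#' and differ only in gradient slope, with a larger within-class spread.
#' @param ... passed on to [synth_config()].
#' @export
synth_config_overlap <- function(...) {
  eff <- list(
    "0%"   = list(mean = 0.30, slope = 0.55, sd = 0.10),
    "40%"  = list(mean = 1.00, slope = 0.45, sd = 0.10),
    "60%"  = list(mean = 1.00, slope = 0.35, sd = 0.10),
    "80%"  = list(mean = 1.00, slope = 0.28, sd = 0.10),
    "100%" = list(mean = 1.00, slope = 0.20, sd = 0.10),
    "120%" = list(mean = 1.00, slope = 0.25, sd = 0.10))
  synth_config(treatment_effects = eff, ...)
}

#' Scenario configuration: spatial-only contrast
#'
#' Two classes with identical mean chlorophyll (hence near-identical
#' whole-leaf mean NDVI) that differ only in the *direction* of the
#' base-to-tip gradient. A mean-NDVI-only classifier is at chance by
#' construction; spatial features (zone means, texture) carry the signal.
#' @param slope magnitude of the gradient slope.
#' @param ... passed on to [synth_config()].
#' @export
synth_config_spatial_contrast <- function(slope = 0.6, ...) {
  eff <- list(
    tipward  = list(mean = 1.0, slope = slope,  sd = 0.05),
    baseward = list(mean = 1.0, slope = -slope, sd = 0.05))
  synth_config(treatments = c("tipward", "baseward"),
               treatment_effects = eff, ...)
}

#' Scenario configuration: mean-separable classes
#'
#' Two classes separated purely by mean chlorophyll, identical spatial
#' structure; the mean-NDVI baseline and the full feature set should perform
#' alike.
#' @param ... passed on to [synth_config()].
#' @export
synth_config_mean_separable <- function(...) {
  eff <- list(
    low  = list(mean = 0.60, slope = 0.30, sd = 0.05),
    high = list(mean = 1.40, slope = 0.30, sd = 0.05))
  synth_config(treatments = c("low", "high"), treatment_effects = eff, ...)
}

#' Generate per-band LED illumination fields
#'
#' Positive low-order polynomial surfaces (plus a vignetting bowl),
#' normalized to mean 1, one per band.
#'
#' @param config a [synth_config()].
#' @param seed optional RNG seed (local to this call).
#' @return Named list of matrices, one per canonical band.
#' @export
make_illumination <- function(config, seed = NULL) {
  .with_seed(seed, {
    h <- config$image_shape[1]; w <- config$image_shape[2]
    xi <- matrix(rep(seq(-1, 1, length.out = w), each = h), h, w)
    eta <- matrix(seq(-1, 1, length.out = h), h, w)
    out <- list()
    for (b in .canonical_bands) {
      surf <- 1 + runif(1, -0.1, 0.1) * xi + runif(1, -0.1, 0.1) * eta
      if (config$illumination_order >= 2) {
        v <- runif(1, 0.05, 0.15)
        surf <- surf + runif(1, -0.05, 0.05) * xi * eta - v * (xi^2 + eta^2)
      }
      surf <- pmax(surf, 0.2)
      out[[b]] <- surf / mean(surf)
    }
    out
  })
}

#' Generate one synthetic leaf scene with ground truth
#'
#' Rasterizes a random lanceolate leaf silhouette (rounded base, pointed
#' tip, slight tilt and arch), a tapering midrib with parallel secondary
#' veins converging toward the tip, a treatment-dependent chlorophyll field
#' (mean scale x base-to-tip gradient x smooth low-frequency texture,
#' reduced on veins, zero off-leaf), `n_threads` straight non-crossing
#' near-vertical guard threads spanning the frame, and per-band illumination
#' surfaces.
#'
#' @param config a [synth_config()].
#' @param treatment treatment label (must be in `config$treatments`).
#' @param seed optional RNG seed; the draw is bit-reproducible given
#'   (config, treatment, seed).
#' @param illumination optional illumination fields (from
#'   [make_illumination()]) shared across a session; generated fresh if NULL.
#' @return A list of class `scene_truth` with elements `leaf_mask`,
#'   `vein_mask`, `thread_mask` (logical matrices), `chlorophyll`,
#'   `illumination`, `treatment`.
#' @export
generate_leaf_scene <- function(config, treatment, seed = NULL,
                                illumination = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!treatment %in% config$treatments)
    stop("unknown treatment: ", treatment)
  .with_seed(seed, {
    h <- config$image_shape[1]; w <- config$image_shape[2]
    if (is.null(illumination)) illumination <- make_illumination(config)
    X <- matrix(rep(seq_len(w), each = h), h, w)
    Y <- matrix(seq_len(h), h, w)

    for (attempt in 1:5) {
      L <- runif(1, 0.72, 0.88) * w
      x0 <- runif(1, 0.04, 0.10) * w
      hw_max <- runif(1, 0.10, 0.16) * h
      y0 <- h / 2 + runif(1, -0.08, 0.08) * h
      tilt <- tan(runif(1, -4, 4) * pi / 180)
      sag <- runif(1, -0.06, 0.06) * h

      u <- (X - x0) / L
      in01 <- u > 0 & u < 1
      uc <- pmin(pmax(u, 0), 1)
      ustar <- 0.35 / 1.10
      fmax <- ustar^0.35 * (1 - ustar)^0.75
      hw_u <- hw_max * (uc^0.35 * (1 - uc)^0.75) / fmax
      cy <- y0 + tilt * L * (u - 0.5) + sag * 4 * u * (1 - u)
      leaf <- in01 & abs(Y - cy) <= hw_u
      if (sum(leaf) >= 0.01 * h * w) break
      if (attempt == 5) stop("degenerate leaf polygon after 5 attempts")
    }

    # veins: midrib along the axis + parallel secondaries that follow the
    # margin taper (so they converge at the tip)
    vein <- in01 & abs(Y - cy) <= (config$midrib_width_px / 2) * (1 - 0.6 * uc)
    K <- config$n_secondary_veins
    if (K > 0) {
      for (k in seq_len(K)) {
        f <- k / (K + 0.7)
        for (s in c(-1, 1)) {
          ctr <- cy + s * f * hw_u
          vein <- vein | (in01 & uc < 0.95 &
                            abs(Y - ctr) <= config$vein_width_px / 2)
        }
      }
    }
    vein <- vein & leaf

    # chlorophyll: treatment mean x base-to-tip gradient x smooth texture
    eff <- config$treatment_effects[[treatment]]
    mean_i <- eff$mean * exp(rnorm(1, 0, eff$sd))
    ubar <- mean(u[leaf])
    grad <- 1 - eff$slope * (u - ubar)
    S <- matrix(0, h, w)
    for (i in 1:3) {
      k <- runif(1, 1.5, 3.5) / max(h, w)
      th <- runif(1, 0, pi)
      S <- S + cos(2 * pi * k * (cos(th) * X + sin(th) * Y) + runif(1, 0, 2 * pi))
    }
    S <- (S - mean(S[leaf])) / sd(S)
    chl <- mean_i * grad * (1 + config$texture_amp * S)
    chl[vein] <- chl[vein] * config$vein_factor
    chl <- pmax(chl, 0)
    chl[!leaf] <- 0

    # guard threads: a comb of non-crossing near-vertical lines
    thread <- matrix(FALSE, h, w)
    if (config$n_threads > 0) {
      for (j in seq_len(config$n_threads)) {
        xc <- w * (j - 0.5) / config$n_threads + runif(1, -0.03, 0.03) * w
        tj <- tan(runif(1, -6, 6) * pi / 180)
        thread <- thread |
          abs(X - (xc + tj * (Y - h / 2))) <= config$thread_width_px / 2
      }
    }

    structure(
      list(leaf_mask = leaf, vein_mask = vein, thread_mask = thread,
           chlorophyll = chl, illumination = illumination,
           treatment = treatment),
      class = "scene_truth")
  })
}

#' Noise-free transmittance of a scene
#'
#' Closed-form Beer-Lambert transmittance per band, the oracle consumed by
#' calibration and reconstruction tests: `T_b = exp(-absorbance_b * chl)`
#' (1 on the background where chlorophyll is 0).
#'
#' @param scene a `scene_truth`.
#' @param config the [synth_config()] used to generate it.
#' @return A [band_stack()] of transmittance values with `bit_depth_max = 1`.
#' @export
transmittance_truth <- function(scene, config) {
  h <- dim(scene$chlorophyll)[1]; w <- dim(scene$chlorophyll)[2]
  px <- array(0, dim = c(h, w, 4))
  for (i in seq_along(.canonical_bands)) {
    b <- .canonical_bands[i]
    px[, , i] <- exp(-config$absorbance_coeffs[[b]] * scene$chlorophyll)
  }
  band_stack(px, bit_depth_max = 1)
}

#' Render a scene into a raw and a white band stack
#'
#' Per band `b`: ideal transmittance `T_b = exp(-absorbance_b * chl)` (1 on
#' background); raw pixel = `bit_depth_max * exposure * illumination_b * T_b`,
#' thread pixels multiplied by the occlusion factor, plus zero-mean Gaussian
#' noise of sd `noise_sd * bit_depth_max`, clipped to `[0, bit_depth_max]`.
#' The white stack is the same without leaf or threads.
#'
#' @param scene a `scene_truth`.
#' @param config the [synth_config()].
#' @param seed optional RNG seed for the noise draw.
#' @param noise_sd override of the config noise level (e.g. 0 for noise-free
#'   renders).
#' @return List with elements `raw` and `white`, both [band_stack()]s.
#' @export
render_stack <- function(scene, config, seed = NULL, noise_sd = config$noise_sd) {
  stopifnot(inherits(scene, "scene_truth"))
  .with_seed(seed, {
    h <- dim(scene$chlorophyll)[1]; w <- dim(scene$chlorophyll)[2]
    bdm <- config$bit_depth_max
    raw <- array(0, dim = c(h, w, 4))
    white <- array(0, dim = c(h, w, 4))
    for (i in seq_along(.canonical_bands)) {
      b <- .canonical_bands[i]
      tb <- exp(-config$absorbance_coeffs[[b]] * scene$chlorophyll)
      plane <- bdm * config$exposure * scene$illumination[[b]] * tb
      plane[scene$thread_mask] <- plane[scene$thread_mask] * config$occlusion_factor
      wplane <- bdm * config$exposure * scene$illumination[[b]]
      if (noise_sd > 0) {
        plane <- plane + rnorm(h * w, 0, noise_sd * bdm)
        wplane <- wplane + rnorm(h * w, 0, noise_sd * bdm)
      }
      raw[, , i] <- pmin(pmax(plane, 0), bdm)
      white[, , i] <- pmin(pmax(wplane, 0), bdm)
    }
    list(raw = band_stack(raw, bit_depth_max = bdm),
         white = band_stack(white, bit_depth_max = bdm))
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes raw stacks (32-bit float multipage TIFF), one shared white stack
#' per session, ground-truth masks (0/255 single-page TIFF) and a manifest
#' CSV. Fully reproducible from the seed: per-image substreams are drawn
#' from one hierarchical stream, so each image is independent of dataset
#' size.
#'
#' @param config a [synth_config()].
#' @param n_per_treatment images per treatment (default 20: 10 plants in
#'   each of 2 plots).
#' @param out_dir writable output directory (created if needed).
#' @param seed integer seed.
#' @return The [load_manifest()]-validated manifest, invisibly the path too.
#' @export
generate_dataset <- function(config, n_per_treatment = 20, out_dir, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  treatments <- config$treatments
  n_total <- length(treatments) * n_per_treatment
  rows <- NULL
  .with_seed(seed, {
    seeds <- sample.int(2^31 - 2, n_total + 1)
    illum <- make_illumination(config, seed = seeds[1])
    if (n_total > 0) {
      white <- .with_seed(seeds[1] + 1, {
        blank <- structure(
          list(leaf_mask = matrix(FALSE, config$image_shape[1], config$image_shape[2]),
               vein_mask = matrix(FALSE, config$image_shape[1], config$image_shape[2]),
               thread_mask = matrix(FALSE, config$image_shape[1], config$image_shape[2]),
               chlorophyll = matrix(0, config$image_shape[1], config$image_shape[2]),
               illumination = illum, treatment = treatments[1]),
          class = "scene_truth")
        render_stack(blank, config)$white
      })
      write_stack(white, file.path(out_dir, "white.tif"))
    }
    idx <- 0
    for (tr in treatments) {
      for (i in seq_len(n_per_treatment)) {
        idx <- idx + 1
        s <- seeds[idx + 1]
        res <- .with_seed(s, {
          scene <- generate_leaf_scene(config, tr, illumination = illum)
          list(scene = scene, stacks = render_stack(scene, config))
        })
        id <- sprintf("img_%03d", idx)
        write_stack(res$stacks$raw, file.path(out_dir, paste0(id, ".tif")))
        write_mask(res$scene$leaf_mask, file.path(out_dir, paste0(id, "_leaf.tif")))
        write_mask(res$scene$vein_mask, file.path(out_dir, paste0(id, "_veins.tif")))
        write_mask(res$scene$thread_mask, file.path(out_dir, paste0(id, "_threads.tif")))
        rows <- rbind(rows, data.frame(
          image_path = paste0(id, ".tif"), white_id = "white",
          treatment = tr, plot = (i - 1) %/% max(1, n_per_treatment %/% 2) + 1,
          plant = i, stringsAsFactors = FALSE))
      }
    }
  })
  if (is.null(rows))
    rows <- data.frame(image_path = character(), white_id = character(),
                       treatment = character(), plot = integer(),
                       plant = integer())
  write.csv(rows, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  load_manifest(file.path(out_dir, "manifest.csv"), treatments = treatments)
}
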