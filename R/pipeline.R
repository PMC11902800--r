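# End-to-end orchestration: raw + white stack -> reconstructed stack ->
# masks -> feature row; and in-memory simulation of whole feature tables.

#' Process one raw image through the full pipeline
#'
#' Calibration, optional thread detection + inpainting, NDVI, leaf
#' segmentation, zoning, vein segmentation and feature extraction.
#'
#' @param raw,white raw and white-reference [band_stack()]s.
#' @param ndvi_threshold leaf segmentation threshold.
#' @param zones `c(n_longitudinal, n_lateral)`.
#' @param detect run thread detection/inpainting (TRUE) or skip it.
#' @param detect_args extra arguments for [detect_threads()].
#' @param glcm_levels GLCM gray levels.
#' @return List: `calibrated`, `thread_mask`, `reconstructed`, `ndvi`,
#'   `leaf`, `zones`, `veins`, `features` (one-row data.frame).
#' @export
process_image <- function(raw, white, ndvi_threshold = 0.1,
                          zones = c(4, 2), detect = TRUE,
                          detect_args = list(), glcm_levels = 16) {
  cal <- calibrate(raw, white)
  if (detect) {
    tm <- do.call(detect_threads, c(list(cal), detect_args))
    rec <- inpaint(cal, tm)
  } else {
    tm <- NULL
    rec <- cal
  }
  nd <- ndvi(rec)
  leaf <- segment_leaf(nd, threshold = ndvi_threshold)
  zs <- zone_leaf(leaf, zones[1], zones[2])
  vn <- segment_veins(rec, leaf)
  feats <- extract_features(rec, leaf, zs, vn, glcm_levels = glcm_levels)
  list(calibrated = cal, thread_mask = tm, reconstructed = rec, ndvi = nd,
       leaf = leaf, zones = zs, veins = vn, features = feats)
}

#' Simulate a labelled feature table in memory
#'
#' Generates `n_per_treatment` scenes per treatment (one shared
#' illumination session and white reference), renders them, runs the full
#' pipeline on each and stacks the feature rows. Reproducible from the
#' seed via per-image substreams.
#'
#' @param config a [synth_config()].
#' @param n_per_treatment images per treatment.
#' @param seed integer seed.
#' @param detect run thread detection + inpainting per image.
#' @param detect_args extra arguments for [detect_threads()] (scaled scenes
#'   need a smaller Gabor wavelength/dilation).
#' @param ndvi_threshold,zones,glcm_levels pipeline parameters.
#' @return `data.frame` with `image_id`, `treatment` and feature columns.
#' @export
simulate_feature_table <- function(config, n_per_treatment = 20, seed = 1,
                                   detect = TRUE, detect_args = NULL,
                                   ndvi_threshold = 0.1, zones = c(4, 2),
                                   glcm_levels = 16) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(detect_args)) {
    wl <- max(3, 2 * config$thread_width_px)
    dil <- if (config$image_shape[1] >= 600) 2 else 1
    detect_args <- list(gabor_wavelength_px = wl, dilation_radius_px = dil)
  }
  treatments <- config$treatments
  n_total <- length(treatments) * n_per_treatment
  rows <- vector("list", n_total)
  .with_seed(seed, {
    seeds <- sample.int(2^31 - 2, n_total + 1)
    illum <- make_illumination(config, seed = seeds[1])
    idx <- 0
    for (tr in treatments) {
      for (i in seq_len(n_per_treatment)) {
        idx <- idx + 1
        res <- .with_seed(seeds[idx + 1], {
          scene <- generate_leaf_scene(config, tr, illumination = illum)
          stk <- render_stack(scene, config)
          white <- render_stack(
            structure(list(leaf_mask = scene$leaf_mask & FALSE,
                           vein_mask = scene$vein_mask & FALSE,
                           thread_mask = scene$thread_mask & FALSE,
                           chlorophyll = scene$chlorophyll * 0,
                           illumination = illum, treatment = tr),
                      class = "scene_truth"), config)$white
          process_image(stk$raw, white, ndvi_threshold = ndvi_threshold,
                        zones = zones, detect = detect,
                        detect_args = detect_args,
                        glcm_levels = glcm_levels)
        })
        rows[[idx]] <- cbind(
          data.frame(image_id = sprintf("img_%03d", idx), treatment = tr,
                     stringsAsFactors = FALSE),
          res$features)
        .log_stage("simulate", "image %d/%d (%s)", idx, n_total, tr)
      }
    }
  })
  out <- do.call(rbind, rows)
  out$treatment <- factor(out$treatment, levels = treatments)
  out
}
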