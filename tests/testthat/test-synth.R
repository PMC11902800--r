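test_that("scenes carry the configured number of separate thread lines", {
  cfg <- small_synth_config()
  sc <- generate_leaf_scene(cfg, "60%", seed = 5)
  expect_equal(max(EBImage::bwlabel(sc$thread_mask + 0)), 5)
  cfg0 <- small_synth_config(n_threads = 0)
  sc0 <- generate_leaf_scene(cfg0, "60%", seed = 5)
  expect_false(any(sc0$thread_mask))
})

test_that("scene truth satisfies its structural invariants", {
  cfg <- small_synth_config()
  for (s in 1:3) {
    sc <- generate_leaf_scene(cfg, "100%", seed = s)
    expect_true(all(sc$leaf_mask[sc$vein_mask]))          # veins inside leaf
    expect_true(all(sc$chlorophyll[!sc$leaf_mask] == 0))  # chl zero off-leaf
    expect_true(all(sc$chlorophyll >= 0))
    for (b in names(sc$illumination)) {
      expect_true(all(sc$illumination[[b]] > 0))
      expect_equal(mean(sc$illumination[[b]]), 1, tolerance = 1e-12)
    }
  }
})

test_that("zero mean chlorophyll scale yields an absorption-free leaf", {
  cfg <- synth_config(image_shape = c(180, 300), n_secondary_veins = 2,
                      treatments = "0%",
                      treatment_effects = list("0%" = list(mean = 0, slope = 0.3,
                                                           sd = 0)))
  sc <- generate_leaf_scene(cfg, "0%", seed = 9)
  expect_true(all(sc$chlorophyll == 0))
  # noise-free, flat illumination: raw equals white off-thread
  sc$illumination <- lapply(sc$illumination, function(x) x * 0 + 1)
  st <- render_stack(sc, cfg, noise_sd = 0)
  off <- !sc$thread_mask
  for (i in 1:4)
    expect_equal(st$raw$pixels[, , i][off], st$white$pixels[, , i][off])
})

test_that("rendering follows the Beer-Lambert closed form", {
  h <- 20; w <- 30
  leaf <- matrix(FALSE, h, w); leaf[5:15, 5:25] <- TRUE
  chl <- matrix(0, h, w); chl[leaf] <- 1
  sc <- manual_scene(h, w, leaf, chl)
  cfg <- synth_config(image_shape = c(h, w), exposure = 1, noise_sd = 0,
                      treatments = "0%",
                      treatment_effects = list("0%" = list(mean = 1, slope = 0,
                                                           sd = 0)))
  st <- render_stack(sc, cfg, noise_sd = 0)
  expect_equal(get_band(st$raw, "red")[10, 10], 255 * exp(-2), tolerance = 1e-12)
  expect_equal(get_band(st$raw, "nir")[10, 10], 255 * exp(-0.05),
               tolerance = 1e-12)
  expect_equal(get_band(st$raw, "red")[1, 1], 255)  # background
  # scalar NDVI oracle for a unit-chlorophyll pixel
  nd <- ndvi(calibrate(st$raw, st$white))
  expect_equal(nd$values[10, 10],
               (exp(-0.05) - exp(-2)) / (exp(-0.05) + exp(-2)),
               tolerance = 1e-12)
})

test_that("thread pixels are attenuated by exactly the occlusion factor", {
  cfg <- small_synth_config()
  sc <- generate_leaf_scene(cfg, "80%", seed = 21)
  st <- render_stack(sc, cfg, noise_sd = 0)
  sc_clean <- sc
  sc_clean$thread_mask <- sc$thread_mask & FALSE
  st_clean <- render_stack(sc_clean, cfg, noise_sd = 0)
  th <- sc$thread_mask
  for (i in 1:4) {
    expect_equal(st$raw$pixels[, , i][th],
                 st_clean$raw$pixels[, , i][th] * cfg$occlusion_factor,
                 tolerance = 1e-12)
    expect_equal(st$raw$pixels[, , i][!th], st_clean$raw$pixels[, , i][!th])
  }
})

test_that("red transmittance falls and NDVI rises monotonically with chlorophyll scale", {
  scales <- c(0.3, 0.7, 1.0, 1.4)
  red_t <- ndvi_m <- numeric(length(scales))
  for (i in seq_along(scales)) {
    cfg <- synth_config(image_shape = c(180, 300), n_secondary_veins = 2,
                        treatments = "x",
                        treatment_effects = list(x = list(mean = scales[i],
                                                          slope = 0.3, sd = 0)))
    sc <- generate_leaf_scene(cfg, "x", seed = 77)
    tt <- transmittance_truth(sc, cfg)
    red_t[i] <- mean(get_band(tt, "red")[sc$leaf_mask])
    ndvals <- (get_band(tt, "nir") - get_band(tt, "red")) /
      (get_band(tt, "nir") + get_band(tt, "red"))
    ndvi_m[i] <- mean(ndvals[sc$leaf_mask])
  }
  expect_true(all(diff(red_t) < 0))
  expect_true(all(diff(ndvi_m) > 0))
})

test_that("identical seeds reproduce scenes, renders and datasets byte-for-byte", {
  cfg <- small_synth_config()
  s1 <- generate_leaf_scene(cfg, "40%", seed = 123)
  s2 <- generate_leaf_scene(cfg, "40%", seed = 123)
  expect_identical(s1, s2)
  r1 <- render_stack(s1, cfg, seed = 9)
  r2 <- render_stack(s2, cfg, seed = 9)
  expect_identical(r1$raw$pixels, r2$raw$pixels)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- generate_dataset(cfg, n_per_treatment = 1, out_dir = d1, seed = 4)
  m2 <- generate_dataset(cfg, n_per_treatment = 1, out_dir = d2, seed = 4)
  expect_equal(nrow(m1), 6)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("an empty dataset produces an empty manifest and no image files", {
  cfg <- small_synth_config()
  d <- withr::local_tempdir()
  m <- generate_dataset(cfg, n_per_treatment = 0, out_dir = d, seed = 1)
  expect_equal(nrow(m), 0)
  expect_equal(list.files(d), "manifest.csv")
})

test_that("config validation rejects inconsistent settings", {
  expect_error(synth_config(n_threads = -1), "n_threads")
  expect_error(synth_config(absorbance_coeffs = c(blue = 1, green = 1,
                                                  red = 0.01, nir = 0.05)),
               "red absorbance")
  expect_error(synth_config(treatments = c("a", "b"),
                            treatment_effects = list(a = list(mean = 1,
                                                              slope = 0, sd = 0))),
               "treatment_effects")
  cfg <- small_synth_config()
  expect_error(generate_leaf_scene(cfg, "150%"), "unknown treatment")
})
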