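# brute-force principal-axis zoning oracle: explicit sums, eigen(), sort()
zone_oracle <- function(mask, n_long, n_lat) {
  idx <- which(mask)
  r <- (idx - 1) %% nrow(mask) + 1
  c <- (idx - 1) %/% nrow(mask) + 1
  x <- c - mean(c); y <- r - mean(r)
  C <- matrix(c(mean(x^2), mean(x * y), mean(x * y), mean(y^2)), 2)
  ev <- eigen(C)
  d1 <- ev$vectors[, 1]
  ang <- atan2(d1[2], d1[1])
  if (ang <= -pi / 2) ang <- ang + pi
  if (ang > pi / 2) ang <- ang - pi
  u <- x * cos(ang) + y * sin(ang)
  v <- -x * sin(ang) + y * cos(ang)
  if (mean(u^3) < 0) { u <- -u; v <- -v }
  bin_of <- function(z, n) {
    rk <- rank(z, ties.method = "first")
    pmin(ceiling(rk * n / length(z)), n)
  }
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[idx] <- (bin_of(u, n_long) - 1L) * n_lat + bin_of(v, n_lat)
  lab
}

test_that("a four-band stack yields exactly six pairwise index heatmaps", {
  set.seed(30)
  s <- band_stack(array(runif(5 * 6 * 4, 0.1, 1), dim = c(5, 6, 4)),
                  bit_depth_max = 1)
  maps <- index_heatmaps(s)
  expect_length(maps, 6)
  expect_named(maps, c("blue_green", "blue_red", "blue_nir",
                       "green_red", "green_nir", "red_nir"))
  expect_error(index_heatmaps(band_stack(array(1, dim = c(4, 4, 1)),
                                         band_names = "red")), "2 bands")
})

test_that("swapping a band pair negates its index map wherever valid", {
  set.seed(31)
  s <- band_stack(array(runif(5 * 6 * 4, 0.1, 1), dim = c(5, 6, 4)),
                  bit_depth_max = 1)
  ab <- index_map(s, "green", "nir")
  ba <- index_map(s, "nir", "green")
  expect_equal(ab$values[ab$valid], -ba$values[ba$valid])
  # a pixel with equal bands maps to 0
  s2 <- band_stack(array(0.4, dim = c(3, 3, 4)), bit_depth_max = 1)
  expect_equal(index_map(s2, "blue", "red")$values, matrix(0, 3, 3))
})

test_that("the (nir, red) heatmap is the NDVI map", {
  set.seed(32)
  s <- band_stack(array(runif(6 * 6 * 4, 0.05, 1), dim = c(6, 6, 4)),
                  bit_depth_max = 1)
  maps <- index_heatmaps(s)
  nd <- ndvi(s)
  expect_equal(maps$red_nir$values, -nd$values)
})

test_that("zoning splits a rectangle into equal quadrants and respects identity", {
  mask <- matrix(FALSE, 40, 60); mask[11:30, 11:50] <- TRUE
  z <- zone_leaf(mask, 2, 2)
  counts <- tabulate(z$labels[z$labels > 0], 4)
  expect_true(max(counts) - min(counts) <= 1)
  expect_equal(sum(counts), sum(mask))
  z1 <- zone_leaf(mask, 1, 1)
  expect_identical(z1$labels == 1L, mask)
  expect_error(zone_leaf(matrix(c(TRUE, TRUE, FALSE, FALSE), 2), 2, 2),
               "exceeds leaf area")
})

test_that("zoning matches the brute-force principal-axis oracle", {
  cfg <- small_synth_config()
  sc <- generate_leaf_scene(cfg, "80%", seed = 61)
  z <- zone_leaf(sc$leaf_mask, 4, 2)
  expect_identical(z$labels, zone_oracle(sc$leaf_mask, 4, 2))
  # zone counts cover the leaf exactly
  expect_equal(sum(tabulate(z$labels[z$labels > 0], 8)), sum(sc$leaf_mask))
})

test_that("zone boundaries rotate with the principal axis", {
  # rasterized rectangle at 0 deg and 30 deg; per-zone counts must agree up
  # to rasterization noise
  h <- 200; w <- 200
  X <- matrix(rep(seq_len(w), each = h), h, w) - 100.5
  Y <- matrix(seq_len(h), h, w) - 100.5
  mask0 <- abs(X) <= 60 & abs(Y) <= 20
  th <- 30 * pi / 180
  Xr <- X * cos(th) + Y * sin(th)
  Yr <- -X * sin(th) + Y * cos(th)
  maskr <- abs(Xr) <= 60 & abs(Yr) <= 20
  c0 <- tabulate(zone_leaf(mask0, 4, 2)$labels, 8) / sum(mask0)
  cr <- tabulate(zone_leaf(maskr, 4, 2)$labels, 8) / sum(maskr)
  expect_equal(c0, cr, tolerance = 0.02)
})

test_that("vein segmentation finds vein pixels and rejects blobs", {
  # constant leaf: no gradients, no veins
  s <- band_stack(array(0.5, dim = c(60, 80, 4)), bit_depth_max = 1)
  mask <- matrix(FALSE, 60, 80); mask[10:50, 10:70] <- TRUE
  expect_false(any(segment_veins(s, mask)$mask))

  # a bright compact disc is excluded by the elongation filter
  px <- array(0.5, dim = c(60, 80, 4))
  disc <- (outer(1:60, rep(1, 80)) - 30)^2 + (outer(rep(1, 60), 1:80) - 40)^2 <= 36
  for (i in 1:4) { p <- px[, , i]; p[disc] <- 0.9; px[, , i] <- p }
  vb <- segment_veins(band_stack(px, bit_depth_max = 1), mask)
  expect_equal(sum(vb$mask & disc), 0)
})

test_that("vein recall and precision hold on a mid-size synthetic scene", {
  cfg <- synth_config(image_shape = c(600, 960))
  sc <- generate_leaf_scene(cfg, "80%", seed = 71)
  st <- render_stack(sc, cfg, noise_sd = 0)
  cal <- calibrate(st$raw, st$white)
  leaf <- segment_leaf(ndvi(cal))
  vn <- segment_veins(cal, leaf)
  expect_gte(mask_recall(vn$mask, sc$vein_mask), 0.7)
  expect_gte(sum(vn$mask & sc$vein_mask) / sum(vn$mask), 0.5)
  expect_true(all(leaf$mask[vn$mask]))  # veins inside leaf
})

test_that("region statistics match the brute-force central-moment oracle", {
  expect_equal(region_statistics(matrix(c(1, 2, 3), 1), matrix(TRUE, 1, 3)),
               list(mean = 2, sd = sqrt(2 / 3), skewness = 0, kurtosis = 1.5 - 3))
  st <- region_statistics(matrix(c(0, 0, 0, 1), 2), matrix(TRUE, 2, 2))
  expect_equal(st$skewness, 1.1547005, tolerance = 1e-7)
  set.seed(40)
  for (i in 1:20) {
    x <- rnorm(sample(5:50, 1))
    plane <- matrix(x, 1)
    got <- region_statistics(plane, matrix(TRUE, 1, length(x)))
    want <- moment_oracle(x)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
    if (requireNamespace("e1071", quietly = TRUE)) {
      expect_equal(got$skewness, e1071::skewness(x, type = 1), tolerance = 1e-10)
      expect_equal(got$kurtosis, e1071::kurtosis(x, type = 1), tolerance = 1e-10)
    }
  }
})

test_that("moment estimates converge for large normal samples", {
  set.seed(41)
  x <- rnorm(1e5)
  st <- region_statistics(matrix(x, 1), matrix(TRUE, 1, length(x)))
  expect_lt(abs(st$skewness), 0.05)
  expect_lt(abs(st$kurtosis), 0.1)
})

test_that("constant regions yield degenerate, not bogus, statistics", {
  st <- region_statistics(matrix(5, 3, 3), matrix(TRUE, 3, 3))
  expect_equal(st$mean, 5); expect_equal(st$sd, 0)
  expect_true(is.na(st$skewness)); expect_true(is.na(st$kurtosis))
  expect_error(region_statistics(matrix(1, 2, 2), matrix(FALSE, 2, 2)),
               "empty region")
})

test_that("GLCM features match closed forms on canonical textures", {
  const <- glcm_features(matrix(3.3, 4, 4), matrix(TRUE, 4, 4), levels = 8)
  expect_equal(const$contrast, 0)
  expect_equal(const$energy, 1)
  expect_equal(const$homogeneity, 1)
  expect_true(is.na(const$correlation))

  checker <- matrix(c(0, 1, 1, 0), 2, 2)
  f <- glcm_features(checker, matrix(TRUE, 2, 2), levels = 2,
                     offsets = list(c(0, 1)))
  expect_equal(f$contrast, 1)  # every horizontal pair differs by one level
})

test_that("GLCM features are invariant under affine rescaling of the plane", {
  set.seed(42)
  plane <- matrix(runif(100), 10, 10)
  region <- matrix(runif(100) > 0.2, 10, 10)
  a <- glcm_features(plane, region, levels = 8)
  b <- glcm_features(3 * plane - 11, region, levels = 8)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("GLCM features equal the exhaustive pair-enumeration oracle", {
  set.seed(43)
  offs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (i in 1:15) {
    plane <- matrix(runif(42), 6, 7)
    region <- matrix(runif(42) > 0.25, 6, 7)
    if (!any(region)) next
    got <- glcm_features(plane, region, levels = 4, offsets = offs)
    want <- glcm_oracle(plane, region, 4, offs)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # offsets larger than the region produce missing values
  tiny <- glcm_features(matrix(1:2, 1), matrix(TRUE, 1, 2), levels = 2,
                        offsets = list(c(5, 5)))
  expect_true(all(is.na(unlist(tiny))))
})

test_that("the feature grid enumerates sources x regions x statistics", {
  cfg <- small_synth_config()
  sc <- generate_leaf_scene(cfg, "100%", seed = 81)
  st <- render_stack(sc, cfg, noise_sd = 0)
  cal <- calibrate(st$raw, st$white)
  leaf <- segment_leaf(ndvi(cal))
  zs <- zone_leaf(leaf, 4, 2)
  vn <- segment_veins(cal, leaf)
  f <- extract_features(cal, leaf, zs, vn)
  grid <- grep("^ndvi__", names(f), invert = TRUE, value = TRUE)
  # enumeration: (4 bands + 6 maps) x (1 leaf + 8 zones + vein + nonvein) x 8
  expect_length(grid, 10 * 11 * 8)
  expect_equal(ncol(f), 881)
  expect_false(any(duplicated(names(f))))

  # determinism: identical inputs give identical rows
  f2 <- extract_features(cal, leaf, zs, vn)
  expect_identical(f, f2)

  # whole-leaf mean of the (nir, red) index equals mean NDVI
  expect_equal(f$ndvi__leaf__mean, -f$idx_red_nir__leaf__mean, tolerance = 1e-12)
})

test_that("empty regions yield explicit missing values", {
  cfg <- small_synth_config()
  sc <- generate_leaf_scene(cfg, "100%", seed = 82)
  st <- render_stack(sc, cfg, noise_sd = 0)
  cal <- calibrate(st$raw, st$white)
  leaf <- segment_leaf(ndvi(cal))
  zs <- zone_leaf(leaf, 4, 2)
  zs$labels[zs$labels == 3L] <- 2L  # force zone 3 empty
  vn <- segment_veins(cal, leaf)
  f <- extract_features(cal, leaf, zs, vn)
  z3 <- grep("__zone3__", names(f), value = TRUE)
  expect_length(z3, 10 * 8)
  expect_true(all(is.na(unlist(f[z3]))))
  expect_false(anyNA(unlist(f[grep("__zone1__", names(f), value = TRUE)])))
})
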