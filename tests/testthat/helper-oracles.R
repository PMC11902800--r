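# Independent oracles and small fixtures, kept deliberately naive so they
# share no code with the implementation they check.

# Small-frame generator config for fast unit tests.
small_synth_config <- function(...) {
  synth_config(image_shape = c(180, 300), n_secondary_veins = 2, ...)
}

# Manually assembled scene with full control over every field; used for
# closed-form render checks (flat illumination, known chlorophyll).
manual_scene <- function(h, w, leaf, chl, thread = NULL, vein = NULL,
                         illum_value = 1) {
  if (is.null(thread)) thread <- matrix(FALSE, h, w)
  if (is.null(vein)) vein <- matrix(FALSE, h, w)
  ill <- lapply(c(blue = 1, green = 2, red = 3, nir = 4),
                function(i) matrix(illum_value, h, w))
  names(ill) <- c("blue", "green", "red", "nir")
  structure(list(leaf_mask = leaf, vein_mask = vein, thread_mask = thread,
                 chlorophyll = chl, illumination = ill, treatment = "0%"),
            class = "scene_truth")
}

# Direct central-moment statistics by explicit summation.
moment_oracle <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m4 <- sum((x - m)^4) / n
  list(mean = m, sd = sqrt(m2),
       skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
       kurtosis = if (m2 > 0) m4 / m2^2 - 3 else NA_real_)
}

# Welch two-sample two-sided t-test by direct evaluation of the statistic
# and the Satterthwaite degrees of freedom.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- sum((x - mean(x))^2) / (nx - 1)
  vy <- sum((y - mean(y))^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  2 * stats::pt(-abs(tstat), df)
}

# Exhaustive-pair GLCM: loops over every pixel and offset, no vectorized
# sharing with the implementation.
glcm_oracle <- function(plane, region, levels, offsets) {
  v <- plane[region]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(plane), ncol(plane))
  for (r in seq_len(nrow(plane))) {
    for (c in seq_len(ncol(plane))) {
      if (region[r, c]) {
        q[r, c] <- if (hi > lo)
          min(floor((plane[r, c] - lo) / (hi - lo) * levels), levels - 1) + 1
        else 1L
      }
    }
  }
  feats <- list(contrast = c(), correlation = c(), energy = c(),
                homogeneity = c())
  for (off in offsets) {
    M <- matrix(0, levels, levels)
    for (r in seq_len(nrow(plane))) {
      for (c in seq_len(ncol(plane))) {
        r2 <- r + off[1]; c2 <- c + off[2]
        if (r2 >= 1 && r2 <= nrow(plane) && c2 >= 1 && c2 <= ncol(plane) &&
            !is.na(q[r, c]) && !is.na(q[r2, c2]))
          M[q[r, c], q[r2, c2]] <- M[q[r, c], q[r2, c2]] + 1
      }
    }
    M <- M + t(M)
    if (sum(M) == 0) next
    P <- M / sum(M)
    contrast <- 0; energy <- 0; homog <- 0; cross <- 0
    pm <- rowSums(P)
    mu <- sum(seq_len(levels) * pm)
    s2 <- sum((seq_len(levels) - mu)^2 * pm)
    for (i in seq_len(levels)) {
      for (j in seq_len(levels)) {
        contrast <- contrast + P[i, j] * (i - j)^2
        energy <- energy + P[i, j]^2
        homog <- homog + P[i, j] / (1 + abs(i - j))
        cross <- cross + P[i, j] * (i - mu) * (j - mu)
      }
    }
    feats$contrast <- c(feats$contrast, contrast)
    feats$energy <- c(feats$energy, energy)
    feats$homogeneity <- c(feats$homogeneity, homog)
    feats$correlation <- c(feats$correlation,
                           if (s2 > 0) cross / s2 else NA_real_)
  }
  if (!length(feats$contrast))
    return(list(contrast = NA_real_, correlation = NA_real_,
                energy = NA_real_, homogeneity = NA_real_))
  lapply(feats, mean)
}

# Ground-truth comparison helpers.
mask_recall <- function(detected, truth) sum(detected & truth) / sum(truth)
mask_fp_fraction <- function(detected, truth) sum(detected & !truth) / length(truth)
mask_jaccard <- function(a, b) sum(a & b) / sum(a | b)

# Directly constructed feature table for classifier unit tests: k classes
# separated in a few informative features, plus noise columns.
toy_feature_table <- function(n_per_class = 15, k = 3, sep = 5, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (cl in seq_len(k)) {
    X <- cbind(matrix(rnorm(n_per_class * 3, mean = cl * sep), n_per_class),
               matrix(rnorm(n_per_class * 5), n_per_class))
    colnames(X) <- paste0("f", 1:8)
    rows[[cl]] <- data.frame(treatment = paste0("c", cl), X)
  }
  out <- do.call(rbind, rows)
  out$treatment <- factor(out$treatment)
  out
}
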