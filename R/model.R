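# Whole-leaf averaged-NDVI baseline and the spatial-spectral random-forest
# classifier with stratified cross-validation.

#' Pairwise significance tests on whole-leaf mean NDVI
#'
#' For every treatment pair, a two-sided Welch (unequal-variance) two-sample
#' t-test on the whole-leaf mean NDVI feature. P-values are reported raw
#' (unadjusted); a Holm-corrected view is attached for reference but not
#' used for the significance flags.
#'
#' @param table feature table (`data.frame`) with a `treatment` column and
#'   the baseline feature column.
#' @param alpha significance level for the flags.
#' @param feature baseline feature column name.
#' @return A list of class `baseline_report`: `means`, `sds` (per
#'   treatment), `p_values` (symmetric matrix), `significant` (logical
#'   matrix at `alpha`), `p_holm`, `alpha`.
#' @export
baseline_ndvi_test <- function(table, alpha = 0.05,
                               feature = "ndvi__leaf__mean") {
  stopifnot(feature %in% names(table), "treatment" %in% names(table))
  groups <- split(table[[feature]], table$treatment, drop = FALSE)
  small <- names(groups)[vapply(groups, length, integer(1)) < 2]
  if (length(small))
    stop("treatment(s) with fewer than 2 samples: ",
         paste(small, collapse = ", "))
  tr <- names(groups)
  k <- length(tr)
  P <- matrix(NA_real_, k, k, dimnames = list(tr, tr))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- t.test(groups[[i]], groups[[j]])$p.value
      P[i, j] <- P[j, i] <- p
    }
  }
  holm <- P
  up <- upper.tri(P)
  holm[up] <- p.adjust(P[up], method = "holm")
  holm[lower.tri(holm)] <- t(holm)[lower.tri(holm)]
  structure(
    list(means = vapply(groups, mean, numeric(1)),
         sds = vapply(groups, sd, numeric(1)),
         p_values = P,
         significant = P < alpha,
         p_holm = holm,
         alpha = alpha),
    class = "baseline_report")
}

#' @export
print.baseline_report <- function(x, ...) {
  cat("<baseline_report> whole-leaf mean NDVI by treatment\n")
  print(round(rbind(mean = x$means, sd = x$sds), 4))
  cat(sprintf("pairwise Welch p-values (flags at alpha = %g):\n", x$alpha))
  print(signif(x$p_values, 3))
  invisible(x)
}

.feature_matrix <- function(table) {
  drop <- intersect(c("image_id", "treatment"), names(table))
  X <- table[, setdiff(names(table), drop), drop = FALSE]
  X <- X[, vapply(X, is.numeric, logical(1)), drop = FALSE]
  as.matrix(X)
}

# Stratified fold assignment: within each class, shuffle and deal folds
# round-robin.
.stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < n_folds)
      stop(sprintf("class '%s' has %d samples, fewer than %d folds; use a smaller n_folds",
                   cl, length(idx), n_folds))
    fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Cross-validated random-forest treatment classification
#'
#' Stratified n-fold cross-validation of a random forest on the full
#' feature table. Per fold, missing features are imputed with the training
#' fold's median (zero if a feature is entirely missing there), a forest is
#' fit on the training folds and the held-out fold is predicted; the
#' confusion matrix is accumulated over folds. Deterministic given the
#' seed (which drives both the fold assignment and the forests).
#'
#' @param table feature table with `treatment` and feature columns.
#' @param n_folds number of CV folds (default 10).
#' @param seed integer seed.
#' @param rf_config list: `ntree` (default 500), `mtry` (default
#'   floor(sqrt(p))), `nodesize` (default 1, i.e. no depth cap).
#' @param features optional character vector restricting the feature
#'   columns used.
#' @return A list of class `class_report`: `confusion` (true x predicted),
#'   `accuracy`, `recall` (per class), `folds` (assignment vector), `seed`,
#'   `n`.
#' @export
train_evaluate <- function(table, n_folds = 10, seed = 1,
                           rf_config = list(), features = NULL) {
  stopifnot("treatment" %in% names(table))
  y <- droplevels(factor(table$treatment))
  X <- .feature_matrix(table)
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(X))
    if (length(missing))
      stop("unknown feature(s): ", paste(missing, collapse = ", "))
    X <- X[, features, drop = FALSE]
  }
  ntree <- rf_config$ntree %||% 500
  nodesize <- rf_config$nodesize %||% 1
  mtry <- rf_config$mtry %||% max(1, floor(sqrt(ncol(X))))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  fold <- .stratified_folds(y, n_folds)
  lev <- levels(y)
  conf <- matrix(0L, length(lev), length(lev), dimnames = list(true = lev,
                                                               predicted = lev))
  for (f in seq_len(n_folds)) {
    tr_i <- fold != f; te_i <- fold == f
    Xtr <- X[tr_i, , drop = FALSE]
    med <- apply(Xtr, 2, function(col) {
      m <- median(col, na.rm = TRUE); if (is.na(m)) 0 else m
    })
    fill <- function(M) {
      for (j in seq_len(ncol(M))) {
        nas <- is.na(M[, j])
        if (any(nas)) M[nas, j] <- med[j]
      }
      M
    }
    rf <- randomForest::randomForest(fill(Xtr), y[tr_i], ntree = ntree,
                                     mtry = min(mtry, ncol(X)),
                                     nodesize = nodesize)
    pred <- predict(rf, fill(X[te_i, , drop = FALSE]))
    conf <- conf + base::table(factor(y[te_i], levels = lev),
                               factor(pred, levels = lev))
  }
  conf <- matrix(as.integer(conf), nrow(conf), ncol(conf),
                 dimnames = dimnames(conf))
  acc <- sum(diag(conf)) / sum(conf)
  recall <- diag(conf) / rowSums(conf)
  structure(list(confusion = conf, accuracy = acc, recall = recall,
                 folds = fold, seed = seed, n = length(y)),
            class = "class_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("<class_report> %d samples, overall accuracy %.3f\n",
              x$n, x$accuracy))
  print(x$confusion)
  cat("per-class recall:\n")
  print(round(x$recall, 3))
  invisible(x)
}

#' Spatial-gain contrast experiment
#'
#' Quantifies what the spatial-spectral features add over the traditional
#' whole-leaf average: runs [train_evaluate()] twice on the same table -
#' once restricted to the whole-leaf mean NDVI feature, once with the full
#' feature set - and returns both cross-validated accuracies.
#'
#' @inheritParams train_evaluate
#' @return List: `accuracy_mean_only`, `accuracy_full`, and the two
#'   `class_report`s.
#' @export
spatial_gain_experiment <- function(table, n_folds = 10, seed = 1) {
  mean_only <- train_evaluate(table, n_folds = n_folds, seed = seed,
                              features = "ndvi__leaf__mean")
  full <- train_evaluate(table, n_folds = n_folds, seed = seed)
  list(accuracy_mean_only = mean_only$accuracy,
       accuracy_full = full$accuracy,
       report_mean_only = mean_only,
       report_full = full)
}
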