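## RBF-SVM training, jackknife evaluation, grid search and the four
## performance metrics. The kernel machine is LIBSVM via e1071; feature
## standardization (z-score, fit on training rows only) is applied before
## the kernel because the 591 features mix entropies, counts and energies
## on very different scales.

#' Binary classification metrics from a confusion matrix
#'
#' Sensitivity, specificity, accuracy, and the Matthews correlation
#' coefficient `((TP*TN) - (FP*FN)) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`;
#' a zero factor in the Mcc denominator yields Mcc = 0 by convention.
#'
#' @param tp,tn,fp,fn Non-negative confusion counts, total > 0.
#' @return A one-row tibble: `tp`, `tn`, `fp`, `fn`, `sn`, `sp`, `acc`, `mcc`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("empty confusion matrix")
  sn <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    sn = sn, sp = sp, acc = (tp + tn) / total, mcc = mcc
  )
}

fit_scaler <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  list(center = center, scale = scale)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, "/")
}

#' Train an RBF-kernel support vector machine
#'
#' @param table Feature tibble with a two-class `label` column.
#' @param cost Soft-margin penalty C (> 0).
#' @param gamma RBF kernel width (> 0); `NULL` (default) uses the LIBSVM
#'   convention 1 / n_features.
#' @param scale Standardize each feature (z-score fit on these training rows)
#'   before the kernel. Recommended; disable to feed raw features.
#' @return A `premir_model` object (LIBSVM fit + scaler + column schema).
#' @export
svm_train <- function(table, cost = 8, gamma = NULL, scale = TRUE) {
  y <- label_factor(table)
  if (nlevels(droplevels(y)) < 2L) stop("training data contains a single class")
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  if (anyNA(X)) stop("missing values in feature table")
  if (is.null(gamma)) gamma <- 1 / length(feats)
  scaler <- if (scale) fit_scaler(X) else NULL
  if (!is.null(scaler)) X <- apply_scaler(X, scaler)
  fit <- e1071::svm(
    x = X, y = y, type = "C-classification", kernel = "radial",
    cost = cost, gamma = gamma, scale = FALSE
  )
  structure(
    list(
      fit = fit, scaler = scaler, features = feats,
      levels = levels(y), cost = cost, gamma = gamma
    ),
    class = "premir_model"
  )
}

#' @export
print.premir_model <- function(x, ...) {
  cat(
    "RBF-SVM on", length(x$features), "features | C =", x$cost,
    ", gamma =", x$gamma, "|", x$fit$tot.nSV, "support vectors\n"
  )
  invisible(x)
}

#' Predict classes for new feature rows
#'
#' @param object A `premir_model`.
#' @param newdata Feature tibble containing the training feature columns.
#' @param ... Unused.
#' @return Factor of predicted labels with the training levels.
#' @export
predict.premir_model <- function(object, newdata, ...) {
  missing_cols <- setdiff(object$features, names(newdata))
  if (length(missing_cols) > 0L) {
    stop("newdata lacks feature column(s): ", paste(utils::head(missing_cols, 5), collapse = ", "))
  }
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  if (!is.null(object$scaler)) X <- apply_scaler(X, object$scaler)
  stats::predict(object$fit, X)
}

#' Jackknife (leave-one-out) evaluation of the RBF-SVM
#'
#' Each row is singled out in turn as the test sample and a model is trained
#' on the remaining rows (n fits in total); metrics come from the pooled
#' confusion matrix. The first factor level of `label` is treated as the
#' positive class by default.
#'
#' @inheritParams svm_train
#' @param positive Label value counted as positive (TP) class; defaults to
#'   the first factor level.
#' @return A one-row metrics tibble (see [classification_metrics()]).
#' @export
svm_jackknife <- function(table, cost = 8, gamma = NULL, scale = TRUE,
                          positive = NULL) {
  y <- label_factor(table)
  n <- nrow(table)
  if (n < 4L || min(table(y)) < 2L) {
    stop("jackknife needs n >= 4 with at least 2 members per class")
  }
  if (is.null(positive)) positive <- levels(y)[1]
  stopifnot(positive %in% levels(y))
  pred <- character(n)
  for (i in seq_len(n)) {
    model <- svm_train(table[-i, , drop = FALSE], cost = cost, gamma = gamma, scale = scale)
    pred[i] <- as.character(predict(model, table[i, , drop = FALSE]))
  }
  truth <- as.character(y)
  classification_metrics(
    tp = sum(pred == positive & truth == positive),
    tn = sum(pred != positive & truth != positive),
    fp = sum(pred == positive & truth != positive),
    fn = sum(pred != positive & truth == positive)
  )
}

#' Grid search for (C, gamma) by stratified cross-validation
#'
#' Evaluates every candidate pair on a stratified k-fold split (folds drawn
#' once from `seed`, so the search is reproducible) and returns the
#' accuracy-maximising pair; ties break toward smaller C, then smaller gamma.
#' The default grid is the classical LIBSVM tool grid,
#' C in 2^(-5), 2^(-3), ..., 2^15 and gamma in 2^(-15), 2^(-13), ..., 2^3.
#'
#' @inheritParams svm_train
#' @param costs,gammas Candidate values.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment.
#' @return List with `cost`, `gamma`, `accuracy`, and the full `grid` tibble.
#' @export
svm_grid_search <- function(table, costs = 2^seq(-5, 15, by = 2),
                            gammas = 2^seq(-15, 3, by = 2),
                            folds = 5L, seed = 1L, scale = TRUE) {
  stopifnot(length(costs) > 0, length(gammas) > 0, all(costs > 0), all(gammas > 0))
  y <- label_factor(table)
  n <- nrow(table)
  fold_id <- integer(n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  grid <- tidyr::expand_grid(cost = sort(costs), gamma = sort(gammas))
  acc <- vapply(seq_len(nrow(grid)), function(r) {
    correct <- 0L
    for (f in seq_len(folds)) {
      test <- fold_id == f
      if (!any(test) || nlevels(droplevels(y[!test])) < 2L) next
      model <- svm_train(table[!test, , drop = FALSE],
        cost = grid$cost[r], gamma = grid$gamma[r], scale = scale
      )
      correct <- correct + sum(predict(model, table[test, , drop = FALSE]) == y[test])
    }
    correct / n
  }, numeric(1))
  grid$accuracy <- acc
  best <- grid[order(-grid$accuracy, grid$cost, grid$gamma), ][1, ]
  list(cost = best$cost, gamma = best$gamma, accuracy = best$accuracy, grid = grid)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
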