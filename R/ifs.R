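#' Incremental feature selection along an mRMR ranking
#'
#' Evaluates nested prefixes S_k of the ranked feature list by jackknife
#' accuracy of the RBF-SVM and reports the accuracy-maximising prefix size
#' (smallest k on ties). `step` evaluates every `step`-th prefix (k = 1,
#' 1+step, ...; the full feature set is always included) to keep the
#' quadratic cost manageable on larger tables.
#'
#' @param table Labelled feature tibble.
#' @param ranking Tibble from [mrmr_rank()] (a permutation of the table's
#'   feature columns).
#' @param cost,gamma,scale SVM configuration (see [svm_train()]).
#' @param step Prefix stride.
#' @return An `ifs_curve` object: tibble `curve` (`k`, `acc`, `mcc`, `sn`,
#'   `sp`), `optimal_k`, and `best_acc`.
#' @export
ifs_select <- function(table, ranking, cost = 8, gamma = NULL, scale = TRUE,
                       step = 1L) {
  feats <- feature_columns(table)
  if (!setequal(ranking$feature, feats)) {
    stop("ranking is not a permutation of the table's feature columns")
  }
  p <- length(feats)
  ks <- unique(c(seq(1L, p, by = as.integer(step)), p))
  rows <- lapply(ks, function(k) {
    cols <- c(intersect(c("id", "label"), names(table)), ranking$feature[seq_len(k)])
    m <- svm_jackknife(table[, cols, drop = FALSE], cost = cost, gamma = gamma, scale = scale)
    dplyr::bind_cols(tibble::tibble(k = k), m[, c("acc", "mcc", "sn", "sp")])
  })
  curve <- dplyr::bind_rows(rows)
  optimal_k <- curve$k[which.max(curve$acc)] # first max = smallest k on ties
  structure(
    list(curve = curve, optimal_k = optimal_k, best_acc = max(curve$acc)),
    class = "ifs_curve"
  )
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat(
    "IFS curve over", nrow(x$curve), "prefix sizes; optimal k =", x$optimal_k,
    "with jackknife accuracy", sprintf("%.4f", x$best_acc), "\n"
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an IFS curve into its per-prefix metrics
#'
#' @param x An `ifs_curve`.
#' @param ... Unused.
#' @return The curve tibble (`k`, `acc`, `mcc`, `sn`, `sp`).
#' @export
tidy.ifs_curve <- function(x, ...) x$curve

#' One-row summary of an IFS run
#'
#' @param x An `ifs_curve`.
#' @param ... Unused.
#' @return Tibble with `optimal_k`, `best_acc`, `n_evaluated`.
#' @export
glance.ifs_curve <- function(x, ...) {
  tibble::tibble(
    optimal_k = x$optimal_k, best_acc = x$best_acc, n_evaluated = nrow(x$curve)
  )
}

#' Plot jackknife accuracy against prefix size
#'
#' @param object An `ifs_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ifs_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$acc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = object$optimal_k, linetype = "dashed") +
    ggplot2::labs(
      x = "number of top-ranked features (k)",
      y = "jackknife accuracy",
      title = "Incremental feature selection"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-feature relevance along the mRMR ranking
#'
#' @param ranking Tibble from [mrmr_rank()].
#' @param top Number of top-ranked features to show.
#' @return A ggplot.
#' @export
plot_ranking <- function(ranking, top = 30L) {
  d <- utils::head(ranking, top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$relevance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "relevance I(f, class) [nats]", y = NULL,
      title = paste("Top", nrow(d), "features by mRMR")
    ) +
    ggplot2::theme_minimal()
}
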