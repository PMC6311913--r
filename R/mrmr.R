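## Minimum-redundancy maximum-relevance feature ranking with the canonical
## 3-bin discretization (mean +/- one standard deviation) and plug-in mutual
## information in nats.

#' Discretize features into three bins at mean +/- one standard deviation
#'
#' @param x Numeric vector.
#' @return Integer vector in 1..3 (a constant column maps to all 2s).
#' @export
discretize3 <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(rep(2L, length(x)))
  }
  findInterval(x, c(m - s, m + s)) + 1L
}

#' Plug-in mutual information of two discrete vectors
#'
#' @param a,b Integer/factor vectors of equal length.
#' @return Mutual information in nats (>= 0).
#' @export
mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pj <- tab / n
  pa <- rowSums(pj)
  pb <- colSums(pj)
  idx <- pj > 0
  sum(pj[idx] * log(pj[idx] / outer(pa, pb)[idx]))
}

## fast MI between one discretized column and many, via 9-cell joint tables
mi_against <- function(d_ref, D, cols) {
  n <- nrow(D)
  base <- 3L * (d_ref - 1L)
  vapply(cols, function(j) {
    joint <- tabulate(base + D[, j], nbins = 9L) / n
    pa <- tabulate(d_ref, nbins = 3L) / n
    pb <- tabulate(D[, j], nbins = 3L) / n
    pe <- as.vector(outer(pa, pb))
    idx <- joint > 0
    sum(joint[idx] * log(joint[idx] / pe[idx]))
  }, numeric(1))
}

#' Rank features by minimum redundancy, maximum relevance
#'
#' Greedy mRMR (difference scheme): the first feature maximises the mutual
#' information I(f, class); each subsequent pick maximises
#' I(f, class) - mean over already-selected g of I(f, g). Features are
#' discretized into three bins at mean +/- sd; MI is the plug-in estimate in
#' nats. Ties break toward the earlier column, so the ranking is
#' deterministic.
#'
#' @param table Feature tibble with a two-class `label` column.
#' @return A tibble with columns `rank`, `feature`, `relevance` (I(f, class))
#'   and `objective` (the greedy criterion value at selection time).
#' @export
mrmr_rank <- function(table) {
  y <- label_factor(table)
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  feats <- feature_columns(table)
  if (length(feats) < 2L) stop("need at least 2 features to rank")
  D <- vapply(feats, function(f) discretize3(table[[f]]), integer(nrow(table)))
  ycode <- as.integer(y)

  relevance <- vapply(seq_along(feats), function(j) {
    mutual_information(D[, j], ycode)
  }, numeric(1))

  p <- length(feats)
  selected <- integer(0)
  objective <- numeric(p)
  redundancy_sum <- numeric(p) # running sum of I(f, g) over selected g
  remaining <- seq_len(p)
  for (step in seq_len(p)) {
    crit <- if (step == 1L) {
      relevance[remaining]
    } else {
      relevance[remaining] - redundancy_sum[remaining] / (step - 1L)
    }
    pick <- remaining[which.max(crit)] # which.max takes the first on ties
    objective[step] <- max(crit)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) > 0L) {
      redundancy_sum[remaining] <- redundancy_sum[remaining] +
        mi_against(D[, pick], D, remaining)
    }
  }

  tibble::tibble(
    rank = seq_len(p),
    feature = feats[selected],
    relevance = relevance[selected],
    objective = objective
  )
}
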