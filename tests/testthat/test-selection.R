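make_labelled_table <- function(n = 60, seed = 17) {
  set.seed(seed)
  label <- rep(c("positive", "negative"), each = n / 2)
  shift <- ifelse(label == "positive", 1.5, 0)
  f1 <- shift + rnorm(n, sd = 0.5) # strong signal
  f3 <- shift * 0.4 + rnorm(n, sd = 0.8) # weaker, partly independent signal
  tibble::tibble(
    id = paste0("s", seq_len(n)), label = label,
    f1 = f1, f2 = f1, f3 = f3
  )
}

test_that("an exact duplicate feature is demoted below an independent informative one", {
  tab <- make_labelled_table()
  rk <- mrmr_rank(tab)
  expect_equal(rk$feature[1], "f1")
  expect_equal(rk$feature[2], "f3")
  expect_equal(rk$feature[3], "f2")

  # brute-force oracle: recompute the greedy objective with an independent MI
  d <- lapply(tab[, c("f1", "f2", "f3")], discretize3)
  y <- tab$label
  rel <- vapply(d, function(f) o_mi(f, y), numeric(1))
  expect_equal(names(which.max(rel)), rk$feature[1])
  obj2 <- vapply(c("f2", "f3"), function(f) rel[[f]] - o_mi(d[[f]], d[["f1"]]), numeric(1))
  expect_equal(names(which.max(obj2)), rk$feature[2])
  # relevance values agree with the oracle estimator
  expect_equal(rk$relevance[1], unname(rel["f1"]), tolerance = 1e-12)
})

test_that("a single informative feature among noise ranks first", {
  set.seed(99)
  n <- 200
  label <- rep(c("positive", "negative"), each = n / 2)
  tab <- tibble::as_tibble(
    stats::setNames(as.data.frame(matrix(rnorm(n * 9), n)), paste0("noise", 1:9))
  )
  tab$signal <- ifelse(label == "positive", 2, 0) + rnorm(n, sd = 0.5)
  tab <- dplyr::bind_cols(tibble::tibble(id = paste0("s", 1:n), label = label), tab)
  rk <- mrmr_rank(tab)
  expect_equal(rk$feature[1], "signal")
})

test_that("the ranking is a permutation and reduces to relevance order without redundancy", {
  tab <- make_labelled_table()
  rk <- mrmr_rank(tab)
  expect_setequal(rk$feature, c("f1", "f2", "f3"))
  expect_equal(nrow(rk), 3)

  # independent features: mRMR order equals pure-relevance order
  set.seed(5)
  n <- 100
  label <- rep(c("positive", "negative"), each = n / 2)
  tab2 <- tibble::tibble(
    id = paste0("s", 1:n), label = label,
    a = ifelse(label == "positive", 2, 0) + rnorm(n, sd = 0.4),
    b = ifelse(label == "positive", 1, 0) + rnorm(n, sd = 0.8),
    c = rnorm(n)
  )
  rk2 <- mrmr_rank(tab2)
  expect_equal(rk2$feature[1], "a")
  rel_order <- order(-rk2$relevance)
  expect_equal(rk2$relevance[1], max(rk2$relevance))
})

test_that("relevance is non-negative and near zero for shuffled labels", {
  set.seed(31)
  n <- 300
  tab <- tibble::tibble(
    id = paste0("s", 1:n),
    label = sample(rep(c("positive", "negative"), each = n / 2)),
    f1 = rnorm(n), f2 = rnorm(n)
  )
  rk <- mrmr_rank(tab)
  expect_true(all(rk$relevance >= 0))
  # plug-in MI bias at n=300 with 3x2 cells is ~ (cells-1)/(2n) ~ 0.003 nats
  expect_true(all(rk$relevance < 0.05))
})

test_that("IFS returns k = 1 when the top feature separates perfectly", {
  set.seed(8)
  n <- 60
  label <- rep(c("positive", "negative"), each = n / 2)
  tab <- tibble::tibble(
    id = paste0("s", 1:n), label = label,
    sep = ifelse(label == "positive", 4, 0) + rnorm(n, sd = 0.5),
    noise = rnorm(n)
  )
  rk <- mrmr_rank(tab)
  expect_equal(rk$feature[1], "sep")
  curve <- ifs_select(tab, rk, step = 1)
  expect_equal(curve$optimal_k, 1)
  expect_equal(curve$curve$acc[1], 1)
  expect_equal(glance(curve)$best_acc, 1)
  expect_equal(nrow(tidy(curve)), 2)
})

test_that("IFS evaluates the full feature set and errors on foreign rankings", {
  tab <- make_labelled_table(n = 24)
  rk <- mrmr_rank(tab)
  curve <- ifs_select(tab, rk, step = 2)
  expect_true(max(curve$curve$k) == 3) # p always included
  expect_true(all(curve$curve$acc >= 0 & curve$curve$acc <= 1))
  rk_bad <- rk
  rk_bad$feature[1] <- "nonexistent"
  expect_error(ifs_select(tab, rk_bad), "permutation")
})

test_that("constant labels and degenerate tables are refused", {
  tab <- make_labelled_table()
  tab$label <- "positive"
  expect_error(mrmr_rank(tab), "2 label classes")
})
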