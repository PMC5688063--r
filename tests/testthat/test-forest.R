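test_that("leaf regression recovers an exact plane and falls back sanely", {
  d <- tibble::tibble(x1 = c(0, 1, 2, 3, 4.5))
  d$y <- 2 * d$x1 + 3
  fit <- fit_leaf(d, "y", "x1")
  expect_false(fit$fallback)
  expect_equal(unname(fit$coefficients), c(3, 2), tolerance = 1e-10)
  # single row: mean fallback equal to that row's target
  one <- fit_leaf(d[3, ], "y", "x1")
  expect_true(one$fallback)
  expect_equal(one$mean, d$y[3])
  # duplicated feature column: rank-deficient design, mean fallback
  d$x2 <- d$x1
  dup <- fit_leaf(d, "y", c("x1", "x2"))
  expect_true(dup$fallback)
  expect_equal(dup$mean, mean(d$y))
  expect_error(fit_leaf(d[0, ], "y", "x1"), "zero rows")
})

test_that("leaf OLS matches an independent normal-equations solve", {
  for (seed in c(1, 2, 3)) {
    d <- random_table(50, p = 4, seed = seed)
    fit <- fit_leaf(d, "y", paste0("x", 1:4))
    beta <- normal_equations_ols(d[paste0("x", 1:4)], d$y)
    expect_equal(unname(fit$coefficients), unname(beta), tolerance = 1e-8)
  }
})

test_that("trees handle constant and step-function targets", {
  d <- tibble::tibble(x1 = runif(30), y = 5)
  tr <- grow_tree(d, "y", "x1", min_leaf_rows = 3, seed = 1)
  expect_identical(tr$root$type, "leaf")
  expect_equal(predict(tr, d), rep(5, 30))
  # step function: the first split must land between the two plateaus
  set.seed(2)
  d <- tibble::tibble(x1 = runif(40))
  d$y <- ifelse(d$x1 > 0.5, 10, 0)
  lo <- max(d$x1[d$x1 <= 0.5]); hi <- min(d$x1[d$x1 > 0.5])
  tr <- grow_tree(d, "y", "x1", max_depth = 1, min_leaf_rows = 3, seed = 1)
  expect_identical(tr$root$type, "split")
  expect_gt(tr$root$threshold, lo)
  expect_lt(tr$root$threshold, hi)
})

test_that("small trees match an exhaustive split-search oracle", {
  for (seed in 1:20) {
    d <- random_table(30, p = 3, seed = seed)
    tr <- grow_tree(d, "y", paste0("x", 1:3), max_depth = 2,
                    min_leaf_rows = 5, mtry = 4, seed = seed,
                    bound_extrapolation = FALSE)
    X <- as.matrix(d[paste0("x", 1:3)])
    orc <- oracle_tree(X, d$y, min_leaf = 5, max_depth = 2)
    expect_equal(tree_splits(tr$root), tree_splits(orc), tolerance = 1e-12)
  }
})

test_that("a degenerate forest is exactly a global OLS", {
  d <- random_table(60, p = 3, seed = 9)
  f <- fit_forest(d, "y", paste0("x", 1:3), n_trees = 1, bootstrap = FALSE,
                  max_depth = 0, seed = 4, bound_extrapolation = FALSE)
  ols <- stats::lm(y ~ x1 + x2 + x3, data = d)
  expect_equal(predict(f, d, clip = FALSE), unname(stats::fitted(ols)),
               tolerance = 1e-10)
})

test_that("forest fits are deterministic in the seed and row-order invariant", {
  d <- random_table(80, p = 3, seed = 5)
  d$pixel <- seq_len(nrow(d))
  f1 <- fit_forest(d, "y", paste0("x", 1:3), n_trees = 5, seed = 11)
  f2 <- fit_forest(d, "y", paste0("x", 1:3), n_trees = 5, seed = 11)
  expect_identical(predict(f1, d), predict(f2, d))
  expect_identical(f1$boot_indices, f2$boot_indices)
  f3 <- fit_forest(d, "y", paste0("x", 1:3), n_trees = 5, seed = 12)
  expect_false(identical(f1$boot_indices, f3$boot_indices))
  # shuffled rows, same pixel ids: identical fit
  shuffled <- d[sample(nrow(d)), ]
  f4 <- fit_forest(shuffled, "y", paste0("x", 1:3), n_trees = 5, seed = 11)
  expect_identical(predict(f1, d), predict(f4, d))
})

test_that("forest predictions average the trees and clip at zero", {
  d <- random_table(80, p = 2, seed = 6)
  f <- fit_forest(d, "y", c("x1", "x2"), n_trees = 2, seed = 3)
  single <- function(i) {
    g <- f
    g$trees <- f$trees[i]
    g$n_trees <- 1L
    predict(g, d, clip = FALSE)
  }
  expect_equal(predict(f, d, clip = FALSE), (single(1) + single(2)) / 2,
               tolerance = 1e-12)
  # negative targets: unclipped predictions go negative, clipped do not
  d$y <- d$y - 10
  fneg <- fit_forest(d, "y", c("x1", "x2"), n_trees = 3, seed = 3)
  expect_true(any(predict(fneg, d, clip = FALSE) < 0))
  expect_true(all(predict(fneg, d) >= 0))
})

test_that("the categorical flag routes rows and stays out of leaf models", {
  set.seed(8)
  d <- tibble::tibble(x1 = runif(120), water = rep(c(TRUE, FALSE), 60))
  d$y <- ifelse(d$water, 2, 100 + 10 * d$x1)
  f <- fit_forest(d, "y", "x1", categorical = "water", n_trees = 10,
                  min_leaf_rows = 5, seed = 2)
  pred_water <- predict(f, tibble::tibble(x1 = 0.5, water = TRUE))
  pred_land <- predict(f, tibble::tibble(x1 = 0.5, water = FALSE))
  expect_lt(abs(pred_water - 2), 1)
  expect_lt(abs(pred_land - 105), 2)
})

test_that("schema mismatches and bad configurations error", {
  d <- random_table(40, p = 2, seed = 1)
  expect_error(fit_forest(d, "y", c("x1", "x9")), "x9")
  expect_error(fit_forest(d, "y", c("x1", "x2"), n_trees = 0), "n_trees")
  f <- fit_forest(d, "y", c("x1", "x2"), n_trees = 2, seed = 1)
  expect_error(predict(f, d["x1"]), "x2")
})

test_that("serialization round-trips predictions bit-exactly", {
  d <- random_table(70, p = 3, seed = 13, water = TRUE)
  f <- fit_forest(d, "y", paste0("x", 1:3), categorical = "water",
                  n_trees = 4, min_leaf_rows = 8, seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  write_forest(f, path)
  g <- read_forest(path)
  expect_identical(predict(g, d), predict(f, d))
  expect_identical(g$boot_indices, f$boot_indices)
  expect_identical(g$schema$features, f$schema$features)
})

test_that("ensemble variance at a fixed point shrinks with more trees", {
  d <- random_table(60, p = 2, seed = 30)
  x0 <- tibble::tibble(x1 = 0.5, x2 = 0.5)
  pred_at <- function(n_trees, seed) {
    predict(fit_forest(d, "y", c("x1", "x2"), n_trees = n_trees,
                       min_leaf_rows = 6, seed = seed), x0)
  }
  v_small <- var(vapply(1:25, function(s) pred_at(2, s), numeric(1)))
  v_large <- var(vapply(1:25, function(s) pred_at(20, s), numeric(1)))
  expect_lt(v_large, v_small)
})

test_that("tidy and glance summarise the ensemble", {
  d <- random_table(60, p = 2, seed = 14)
  f <- fit_forest(d, "y", c("x1", "x2"), n_trees = 3, min_leaf_rows = 6,
                  seed = 2)
  td <- tidy(f)
  expect_identical(nrow(td), 3L)
  expect_true(all(td$n_leaves >= 1))
  gl <- glance(f)
  expect_identical(gl$n_trees, 3L)
  expect_identical(gl$n_rows, 60L)
})
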