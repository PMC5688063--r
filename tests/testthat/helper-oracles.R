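# Independent oracles the forest implementation is checked against.
# They share no code with R/forest.R: OLS goes through the explicit
# normal equations, and the tree oracle enumerates every (feature,
# threshold) candidate by brute force.

# Normal-equations OLS: beta = (X'X)^-1 X'y with an explicit intercept.
normal_equations_ols <- function(X, y) {
  Z <- cbind(1, as.matrix(X))
  solve(t(Z) %*% Z, t(Z) %*% y)[, 1]
}

# Exhaustive split search mirroring the published split rules:
# variance-reduction criterion, midpoint thresholds, both children at
# least min_leaf rows, ties broken by lowest feature id then lowest
# threshold, recursion to max_depth. Sum of squares is computed
# directly (not from cumulative sums).
oracle_best_split <- function(X, y, min_leaf) {
  n <- length(y)
  ss <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  ss_total <- ss(y)
  tol <- max(1e-12 * abs(ss_total), 1e-12)
  best <- NULL
  best_gain <- 0
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    thresholds <- (xs[-length(xs)] + xs[-1]) / 2
    for (th in thresholds) {
      left <- X[, j] <= th
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      gain <- ss_total - ss(y[left]) - ss(y[!left])
      if (gain > best_gain + tol) {
        best_gain <- gain
        best <- list(feature = j, threshold = th, left = left)
      }
    }
  }
  best
}

oracle_tree <- function(X, y, min_leaf, max_depth, depth = 0) {
  if (depth >= max_depth || length(y) < 2 * min_leaf ||
      isTRUE(all.equal(stats::var(y), 0))) {
    return(list(type = "leaf", n = length(y)))
  }
  sp <- oracle_best_split(X, y, min_leaf)
  if (is.null(sp)) return(list(type = "leaf", n = length(y)))
  list(type = "split", feature = sp$feature, threshold = sp$threshold,
       left = oracle_tree(X[sp$left, , drop = FALSE], y[sp$left],
                          min_leaf, max_depth, depth + 1),
       right = oracle_tree(X[!sp$left, , drop = FALSE], y[!sp$left],
                           min_leaf, max_depth, depth + 1))
}

# Flatten a tree's internal nodes to (feature, threshold) rows in
# depth-first order, for structural comparison.
tree_splits <- function(node) {
  if (node$type == "leaf") return(NULL)
  rbind(c(node$feature, node$threshold),
        tree_splits(node$left), tree_splits(node$right))
}
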