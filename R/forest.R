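#' Fit the linear model held in a terminal node
#'
#' Ordinary least squares of the target on all continuous features. When
#' the node holds too few rows to determine the coefficients
#' (`n < n_features + 2`) or the design matrix is rank-deficient, the
#' leaf falls back to the (weighted) mean of the target and the fallback
#' flag is set.
#'
#' @param data Data frame holding the node's rows.
#' @param target Name of the target column.
#' @param features Character vector of continuous feature columns.
#' @param weights Optional per-row weights (default 1).
#' @return A list: `coefficients` (named, intercept first; `NULL` when the
#'   fallback is used), `mean` (fallback prediction), `fallback` (logical),
#'   `n` (rows used).
#' @export
fit_leaf <- function(data, target, features, weights = NULL) {
  y <- data[[target]]
  n <- length(y)
  if (n == 0) stop("fit_leaf() called with zero rows", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  X <- as.matrix(data[features])
  leaf_fit(X, y, weights)
}

# Internal matrix-level leaf fit shared with the tree grower. Besides
# the OLS coefficients the leaf keeps its target range: leaf predictions
# are later clamped to that range (stretched by 10%), the usual guard in
# model-tree methods against linear extrapolation along poorly
# determined directions of a collinear design.
leaf_fit <- function(X, y, w) {
  n <- length(y)
  p <- ncol(X)
  wmean <- sum(w * y) / sum(w)
  ymin <- min(y); ymax <- max(y)
  margin <- 0.10 * (ymax - ymin)
  bounds <- c(ymin - margin, ymax + margin)
  if (n < p + 2) {
    return(list(coefficients = NULL, mean = wmean, fallback = TRUE, n = n,
                bounds = bounds))
  }
  Z <- cbind(`(Intercept)` = 1, X) * sqrt(w)
  qz <- qr(Z)
  if (qz$rank < p + 1) {
    return(list(coefficients = NULL, mean = wmean, fallback = TRUE, n = n,
                bounds = bounds))
  }
  beta <- qr.coef(qz, y * sqrt(w))
  list(coefficients = beta, mean = wmean, fallback = FALSE, n = n,
       bounds = bounds)
}

# Weighted sum-of-squares about the weighted mean from cumulative sums.
node_ss <- function(sw, swy, swy2) swy2 - swy^2 / sw

# Find the best (feature, threshold) split at one node.
#
# cand: integer ids of candidate features; ids 1..p are columns of X,
# id p+1 (when present) is the binary categorical flag. Ties in the
# criterion are broken toward the lowest feature id, then the lowest
# threshold: features are scanned in increasing id order and thresholds
# in increasing order, and only strict improvements are accepted.
best_split <- function(X, flag, y, w, idx, cand, min_leaf) {
  n <- length(idx)
  sw_t <- sum(w[idx]); swy_t <- sum(w[idx] * y[idx])
  swy2_t <- sum(w[idx] * y[idx]^2)
  ss_total <- node_ss(sw_t, swy_t, swy2_t)
  best <- list(gain = 0)
  tol <- max(1e-12 * abs(ss_total), 1e-12)
  p <- ncol(X)
  for (j in sort(cand)) {
    if (j <= p) {
      xj <- X[idx, j]
      ord <- order(xj, method = "radix")
      xs <- xj[ord]
      ys <- y[idx][ord]; ws <- w[idx][ord]
      cw <- cumsum(ws); cwy <- cumsum(ws * ys); cwy2 <- cumsum(ws * ys^2)
      k <- seq_len(n - 1)
      valid <- (xs[k] < xs[k + 1]) & (k >= min_leaf) & ((n - k) >= min_leaf)
      if (!any(valid)) next
      ss_l <- node_ss(cw[k], cwy[k], cwy2[k])
      ss_r <- node_ss(sw_t - cw[k], swy_t - cwy[k], swy2_t - cwy2[k])
      gain <- ss_total - ss_l - ss_r
      gain[!valid] <- -Inf
      kbest <- which(gain > best$gain + tol)
      if (length(kbest) > 0) {
        kbest <- kbest[which.max(gain[kbest])]
        # lowest threshold among exact ties within this feature
        ties <- which(abs(gain - gain[kbest]) <= tol & valid)
        kbest <- ties[1]
        best <- list(
          gain = gain[kbest], feature = j,
          threshold = (xs[kbest] + xs[kbest + 1]) / 2,
          left = idx[ord[seq_len(kbest)]],
          right = idx[ord[seq(kbest + 1, n)]]
        )
      }
    } else {
      fl <- flag[idx]
      n_r <- sum(fl)
      if (n_r < min_leaf || (n - n_r) < min_leaf) next
      sw_r <- sum(w[idx][fl]); swy_r <- sum((w * y)[idx][fl])
      swy2_r <- sum((w * y^2)[idx][fl])
      ss_r <- node_ss(sw_r, swy_r, swy2_r)
      ss_l <- node_ss(sw_t - sw_r, swy_t - swy_r, swy2_t - swy2_r)
      gain <- ss_total - ss_l - ss_r
      if (gain > best$gain + tol) {
        best <- list(gain = gain, feature = j, threshold = NA_real_,
                     left = idx[!fl], right = idx[fl])
      }
    }
  }
  if (is.null(best$feature)) NULL else best
}

grow_node <- function(X, flag, y, w, idx, depth, params) {
  p <- ncol(X)
  p_total <- p + as.integer(!is.null(flag))
  make_leaf <- function(idx) {
    fit <- leaf_fit(X[idx, , drop = FALSE], y[idx], w[idx])
    list(type = "leaf", coefficients = fit$coefficients, mean = fit$mean,
         fallback = fit$fallback, n = fit$n,
         bounds = if (params$bound_extrapolation) fit$bounds else NULL)
  }
  if (depth >= params$max_depth || length(idx) < 2 * params$min_leaf_rows ||
      stats::var(y[idx]) == 0 || is.na(stats::var(y[idx]))) {
    return(make_leaf(idx))
  }
  cand <- sample.int(p_total, min(params$mtry, p_total))
  sp <- best_split(X, flag, y, w, idx, cand, params$min_leaf_rows)
  if (is.null(sp)) return(make_leaf(idx))
  node <- list(
    type = "split",
    feature = sp$feature,
    threshold = sp$threshold,
    categorical = sp$feature > p,
    left = grow_node(X, flag, y, w, sp$left, depth + 1, params),
    right = grow_node(X, flag, y, w, sp$right, depth + 1, params)
  )
  if (params$smoothing > 0) {
    # internal-node regression used for path smoothing at predict time
    fit <- leaf_fit(X[idx, , drop = FALSE], y[idx], w[idx])
    node$model <- list(coefficients = fit$coefficients, mean = fit$mean,
                       fallback = fit$fallback, n = fit$n,
                       bounds = if (params$bound_extrapolation) fit$bounds
                                else NULL)
  }
  node
}

#' Grow a single model tree
#'
#' Greedy recursive binary splitting: each node evaluates `mtry` randomly
#' drawn candidate features and takes the (feature, threshold) pair with
#' the largest reduction in the target's sum of squares; growth stops at
#' `max_depth`, when a child would fall below `min_leaf_rows`, or when no
#' split reduces the sum of squares. Each terminal node then receives an
#' OLS fit on all continuous features ([fit_leaf()]). Continuous splits
#' place the threshold at the midpoint of adjacent sorted values; the
#' single binary categorical feature (the open-water flag) splits on flag
#' membership and is excluded from leaf regressions.
#'
#' @inheritParams fit_forest
#' @return A `model_tree` object (nested list of nodes).
#' @export
grow_tree <- function(data, target, features, categorical = NULL,
                      weights = NULL, mtry = NULL, max_depth = 12,
                      min_leaf_rows = NULL, seed = NULL,
                      bound_extrapolation = TRUE, smoothing = 0) {
  sc <- forest_schema(data, target, features, categorical)
  params <- forest_params(length(sc$features), mtry, max_depth,
                          min_leaf_rows, bound_extrapolation, smoothing)
  X <- as.matrix(data[sc$features])
  flag <- if (is.null(sc$categorical)) NULL else as.logical(data[[sc$categorical]])
  y <- data[[target]]
  w <- if (is.null(weights)) rep(1, length(y)) else weights
  if (length(y) < params$min_leaf_rows) {
    stop("fewer rows (", length(y), ") than min_leaf_rows (",
         params$min_leaf_rows, ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  root <- grow_node(X, flag, y, w, seq_along(y), 0L, params)
  structure(list(root = root, schema = sc, params = params),
            class = "model_tree")
}

forest_schema <- function(data, target, features, categorical) {
  stopifnot(is.data.frame(data), target %in% names(data))
  missing_f <- setdiff(features, names(data))
  if (length(missing_f) > 0) {
    stop("feature column(s) not in data: ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(categorical) && !categorical %in% names(data)) {
    stop("categorical column '", categorical, "' not in data", call. = FALSE)
  }
  list(target = target, features = features, categorical = categorical)
}

forest_params <- function(p, mtry, max_depth, min_leaf_rows,
                          bound_extrapolation = TRUE, smoothing = 0) {
  p_total <- p + 1L # + categorical flag slot
  if (is.null(mtry)) mtry <- ceiling(sqrt(p_total))
  if (is.null(min_leaf_rows)) min_leaf_rows <- 2L * (p + 1L)
  stopifnot(mtry >= 1, max_depth >= 0, min_leaf_rows >= 1, smoothing >= 0)
  list(mtry = as.integer(mtry), max_depth = as.integer(max_depth),
       min_leaf_rows = as.integer(min_leaf_rows),
       bound_extrapolation = isTRUE(bound_extrapolation),
       smoothing = smoothing)
}

#' Fit a bagged model-tree ensemble
#'
#' The ensemble couples bagging with model trees: each of `n_trees` trees
#' is grown on a bootstrap resample (with replacement, same size as the
#' table) of the training rows, and the ensemble prediction is the
#' arithmetic mean over trees. Rows are canonicalised (sorted by the
#' `pixel` column when present) before fitting, so the fit is invariant
#' to input row shuffling. All randomness flows from `seed`: per-tree
#' substream seeds are drawn once up front, so trees are reproducible
#' independently of evaluation order.
#'
#' @param data Training data frame; rows with a missing target or missing
#'   feature values are dropped (the count is recorded).
#' @param target Name of the target column (Mg C ha^-1).
#' @param features Character vector of continuous feature columns
#'   (monthly climatology layers and latitude in the biomass pipeline).
#' @param categorical Optional name of a single logical column (the
#'   open-water flag); used for splitting only, never in leaf regressions.
#' @param weights Optional per-row weights.
#' @param n_trees Number of trees (default 1000).
#' @param mtry Candidate features per split; default `ceiling(sqrt(p))`
#'   over all features including the categorical flag.
#' @param max_depth Maximum tree depth (default 12; 0 gives a single leaf).
#' @param min_leaf_rows Minimum rows per leaf; default
#'   `2 * (n_features + 1)` so leaf regressions are at worst barely
#'   determined.
#' @param bootstrap Resample rows per tree (default `TRUE`); with `FALSE`
#'   every tree sees the full table.
#' @param seed Master seed (integer).
#' @param bound_extrapolation Clamp each leaf's linear prediction to the
#'   leaf's training-target range stretched by 10% (default `TRUE`), the
#'   usual model-tree guard against runaway extrapolation when leaf
#'   designs are collinear. Set `FALSE` for pure unbounded OLS leaves.
#' @param smoothing Model-tree smoothing constant k (default 0 = off).
#'   With k > 0 each prediction is blended with the regressions fitted
#'   at the ancestor nodes on the way to the root,
#'   `p <- (n_child p + k q_node) / (n_child + k)`: ancestor models see
#'   wider target ranges, which extends principled linear extrapolation
#'   beyond the terminal leaf's clamp near the edge of the training
#'   envelope.
#' @return A `model_tree_forest` object.
#' @examples
#' d <- tibble::tibble(x1 = runif(80), x2 = runif(80))
#' d$y <- 2 * d$x1 + 3 + rnorm(80, sd = 0.1)
#' f <- fit_forest(d, "y", c("x1", "x2"), n_trees = 10, seed = 1)
#' head(predict(f, d))
#' @export
fit_forest <- function(data, target, features, categorical = NULL,
                       weights = NULL, n_trees = 1000, mtry = NULL,
                       max_depth = 12, min_leaf_rows = NULL,
                       bootstrap = TRUE, seed = 1,
                       bound_extrapolation = TRUE, smoothing = 0) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  n_trees <- as.integer(n_trees)
  sc <- forest_schema(data, target, features, categorical)
  if ("pixel" %in% names(data)) data <- dplyr::arrange(data, .data$pixel)
  used_cols <- c(sc$features, sc$target, sc$categorical)
  complete <- stats::complete.cases(data[used_cols])
  n_dropped <- sum(!complete)
  data <- data[complete, , drop = FALSE]
  if (!is.null(weights)) weights <- weights[complete]
  params <- forest_params(length(sc$features), mtry, max_depth,
                          min_leaf_rows, bound_extrapolation, smoothing)
  n <- nrow(data)
  if (n < params$min_leaf_rows) {
    stop("too few complete training rows (", n, ") for min_leaf_rows = ",
         params$min_leaf_rows, call. = FALSE)
  }
  X <- as.matrix(data[sc$features])
  flag <- if (is.null(sc$categorical)) NULL else as.logical(data[[sc$categorical]])
  y <- data[[sc$target]]
  w <- if (is.null(weights)) rep(1, n) else weights

  set.seed(as.integer(seed))
  tree_seeds <- sample.int(.Machine$integer.max, n_trees)
  trees <- vector("list", n_trees)
  boot_idx <- vector("list", n_trees)
  for (b in seq_len(n_trees)) {
    set.seed(tree_seeds[b])
    idx <- if (bootstrap) sort(sample.int(n, n, replace = TRUE)) else seq_len(n)
    boot_idx[[b]] <- idx
    trees[[b]] <- grow_node(X, flag, y, w, idx, 0L, params)
  }
  structure(
    list(trees = trees, boot_indices = boot_idx, schema = sc,
         params = params, n_trees = n_trees, bootstrap = bootstrap,
         seed = as.integer(seed), tree_seeds = tree_seeds,
         n_rows = n, n_dropped = n_dropped),
    class = "model_tree_forest"
  )
}

# Evaluate one node-level model record (leaf or internal) on rows idx.
model_pred <- function(m, X, idx) {
  if (m$fallback) {
    pred <- rep(m$mean, length(idx))
  } else {
    pred <- drop(cbind(1, X[idx, , drop = FALSE]) %*% m$coefficients)
  }
  if (!is.null(m$bounds)) pred <- pmin(pmax(pred, m$bounds[1]), m$bounds[2])
  pred
}

node_n <- function(node) if (node$type == "leaf") node$n else node$model$n

# Route rows down one tree; returns the per-row prediction. With
# smoothing k > 0, child predictions are blended with each ancestor
# node's own regression on the way back up (the classic model-tree
# smoothing pass): p <- (n_child * p + k * q_node) / (n_child + k).
predict_node <- function(node, X, flag, idx, out, k = 0) {
  if (node$type == "leaf") {
    out[idx] <- model_pred(node, X, idx)
    return(out)
  }
  go_right <- if (node$categorical) flag[idx] else X[idx, node$feature] > node$threshold
  if (any(!go_right)) out <- predict_node(node$left, X, flag, idx[!go_right], out, k)
  if (any(go_right)) out <- predict_node(node$right, X, flag, idx[go_right], out, k)
  if (k > 0 && !is.null(node$model)) {
    q <- model_pred(node$model, X, idx)
    n_child <- ifelse(go_right, node_n(node$right), node_n(node$left))
    out[idx] <- (n_child * out[idx] + k * q) / (n_child + k)
  }
  out
}

#' Predict from a model-tree ensemble
#'
#' Mean over trees of each tree's leaf prediction; output is clipped at
#' zero (biomass density cannot be negative).
#'
#' @param object A `model_tree_forest`.
#' @param newdata Data frame carrying the training feature columns.
#' @param clip Clip predictions at zero (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of predictions, Mg C ha^-1.
#' @export
predict.model_tree_forest <- function(object, newdata, clip = TRUE, ...) {
  sc <- object$schema
  missing_f <- setdiff(c(sc$features, sc$categorical), names(newdata))
  if (length(missing_f) > 0) {
    stop("newdata lacks feature column(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(newdata[sc$features])
  flag <- if (is.null(sc$categorical)) NULL else as.logical(newdata[[sc$categorical]])
  n <- nrow(X)
  k <- object$params$smoothing
  if (is.null(k)) k <- 0
  acc <- numeric(n)
  for (tree in object$trees) {
    acc <- acc + predict_node(tree, X, flag, seq_len(n), numeric(n), k)
  }
  pred <- acc / object$n_trees
  if (clip) pred <- pmax(pred, 0)
  pred
}

#' @export
predict.model_tree <- function(object, newdata, clip = TRUE, ...) {
  sc <- object$schema
  X <- as.matrix(newdata[sc$features])
  flag <- if (is.null(sc$categorical)) NULL else as.logical(newdata[[sc$categorical]])
  k <- object$params$smoothing
  if (is.null(k)) k <- 0
  pred <- predict_node(object$root, X, flag, seq_len(nrow(X)),
                       numeric(nrow(X)), k)
  if (clip) pred <- pmax(pred, 0)
  pred
}

#' @export
print.model_tree_forest <- function(x, ...) {
  cat(sprintf(
    "<model_tree_forest> %d trees on %d rows, %d continuous features%s\n",
    x$n_trees, x$n_rows, length(x$schema$features),
    if (is.null(x$schema$categorical)) "" else " + 1 categorical"))
  cat(sprintf("  mtry %d, max_depth %d, min_leaf_rows %d, seed %d\n",
              x$params$mtry, x$params$max_depth, x$params$min_leaf_rows,
              x$seed))
  invisible(x)
}

tree_stats <- function(node, depth = 0L) {
  if (node$type == "leaf") {
    return(list(leaves = 1L, fallback = as.integer(node$fallback),
                depth = depth))
  }
  l <- tree_stats(node$left, depth + 1L)
  r <- tree_stats(node$right, depth + 1L)
  list(leaves = l$leaves + r$leaves, fallback = l$fallback + r$fallback,
       depth = max(l$depth, r$depth))
}

#' Tidy a model-tree ensemble
#'
#' One row per tree: leaf count, depth, and how many leaves fell back to
#' a mean because their regression was under-determined.
#'
#' @param x A `model_tree_forest`.
#' @param ... Unused.
#' @return A tibble with columns `tree`, `n_leaves`, `depth`,
#'   `n_fallback_leaves`, `n_boot_unique`.
#' @export
tidy.model_tree_forest <- function(x, ...) {
  stats <- purrr::map(x$trees, tree_stats)
  tibble::tibble(
    tree = seq_len(x$n_trees),
    n_leaves = purrr::map_int(stats, "leaves"),
    depth = purrr::map_int(stats, ~ as.integer(.x$depth)),
    n_fallback_leaves = purrr::map_int(stats, "fallback"),
    n_boot_unique = purrr::map_int(x$boot_indices, ~ length(unique(.x)))
  )
}

#' Glance at a model-tree ensemble
#'
#' @param x A `model_tree_forest`.
#' @param ... Unused.
#' @return A one-row tibble of hyperparameters and fit-time facts.
#' @export
glance.model_tree_forest <- function(x, ...) {
  tibble::tibble(
    n_trees = x$n_trees, n_rows = x$n_rows, n_dropped = x$n_dropped,
    n_features = length(x$schema$features),
    mtry = x$params$mtry, max_depth = x$params$max_depth,
    min_leaf_rows = x$params$min_leaf_rows,
    bootstrap = x$bootstrap, seed = x$seed
  )
}

# Reals in the JSON document are encoded as decimal strings with 17
# significant digits, which round-trip IEEE doubles exactly; JSON number
# emitters commonly stop at 15 and would perturb restored predictions.
enc_real <- function(x) {
  if (is.null(x)) return(NULL)
  ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
}
dec_real <- function(x, names = NULL) {
  if (is.null(x)) return(NULL)
  x <- unlist(x)
  out <- ifelse(is.na(x) | x == "NA", NA_real_, suppressWarnings(as.numeric(x)))
  if (!is.null(names)) names(out) <- names
  out
}

serialize_node <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf",
         coefficient_names = if (is.null(node$coefficients)) NULL else
           names(node$coefficients),
         coefficients = enc_real(unname(node$coefficients)),
         mean = enc_real(node$mean), fallback = node$fallback, n = node$n,
         bounds = enc_real(node$bounds))
  } else {
    rec <- list(type = "split", feature = node$feature,
                threshold = enc_real(node$threshold),
                categorical = node$categorical,
                left = serialize_node(node$left),
                right = serialize_node(node$right))
    if (!is.null(node$model)) {
      m <- node$model
      rec$model <- list(
        coefficient_names = if (is.null(m$coefficients)) NULL else
          names(m$coefficients),
        coefficients = enc_real(unname(m$coefficients)),
        mean = enc_real(m$mean), fallback = m$fallback, n = m$n,
        bounds = enc_real(m$bounds))
    }
    rec
  }
}

deserialize_node <- function(rec) {
  if (rec$type == "leaf") {
    list(type = "leaf",
         coefficients = dec_real(rec$coefficients,
                                 unlist(rec$coefficient_names)),
         mean = dec_real(rec$mean),
         fallback = rec$fallback, n = rec$n,
         bounds = dec_real(rec$bounds))
  } else {
    th <- dec_real(rec$threshold)
    node <- list(type = "split", feature = rec$feature,
                 threshold = if (is.null(th)) NA_real_ else th,
                 categorical = rec$categorical,
                 left = deserialize_node(rec$left),
                 right = deserialize_node(rec$right))
    if (!is.null(rec$model)) {
      node$model <- list(
        coefficients = dec_real(rec$model$coefficients,
                                unlist(rec$model$coefficient_names)),
        mean = dec_real(rec$model$mean), fallback = rec$model$fallback,
        n = rec$model$n, bounds = dec_real(rec$model$bounds))
    }
    node
  }
}

#' Serialize a forest to JSON / restore it
#'
#' The on-disk format is a versioned JSON document holding the
#' hyperparameters, feature schema, bootstrap indices and nested node
#' records. Numbers are written at full precision, so predictions from a
#' restored forest are bit-identical to the original's.
#'
#' @param forest A `model_tree_forest`.
#' @param path File path.
#' @return `read_forest()` returns the restored `model_tree_forest`;
#'   `write_forest()` returns `path` invisibly.
#' @export
write_forest <- function(forest, path) {
  stopifnot(inherits(forest, "model_tree_forest"))
  doc <- list(
    schema_version = 1L,
    schema = forest$schema,
    params = forest$params,
    n_trees = forest$n_trees,
    bootstrap = forest$bootstrap,
    seed = forest$seed,
    tree_seeds = forest$tree_seeds,
    n_rows = forest$n_rows,
    n_dropped = forest$n_dropped,
    boot_indices = forest$boot_indices,
    trees = purrr::map(forest$trees, serialize_node)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version != 1L) {
    stop("unsupported forest schema version", call. = FALSE)
  }
  sc <- list(target = doc$schema$target,
             features = unlist(doc$schema$features),
             categorical = doc$schema$categorical)
  params <- list(mtry = as.integer(doc$params$mtry),
                 max_depth = as.integer(doc$params$max_depth),
                 min_leaf_rows = as.integer(doc$params$min_leaf_rows),
                 bound_extrapolation = isTRUE(doc$params$bound_extrapolation),
                 smoothing = if (is.null(doc$params$smoothing)) 0 else
                   as.numeric(doc$params$smoothing))
  structure(
    list(trees = purrr::map(doc$trees, deserialize_node),
         boot_indices = purrr::map(doc$boot_indices, ~ as.integer(unlist(.x))),
         schema = sc, params = params,
         n_trees = as.integer(doc$n_trees),
         bootstrap = isTRUE(doc$bootstrap),
         seed = as.integer(doc$seed),
         tree_seeds = as.integer(unlist(doc$tree_seeds)),
         n_rows = as.integer(doc$n_rows),
         n_dropped = as.integer(doc$n_dropped)),
    class = "model_tree_forest"
  )
}
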