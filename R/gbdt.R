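#' Hyperparameters for the boosted-tree engine
#'
#' @param n_trees Number of boosting iterations M (default 5000).
#' @param learning_rate Shrinkage xi in (0, 1] applied to every tree's
#'   contribution (default 0.001).  Lower rates need more trees but
#'   regularise the fit.
#' @param max_depth Maximum depth of each regression tree (default 3).
#' @param min_leaf Minimum observations per leaf (default 5).
#' @param n_folds Folds for [cross_validate_gbdt()] (default 5).
#' @param seed Integer seed for fold shuffling.
#' @return A validated `gbdt_control` list.
#' @export
gbdt_control <- function(n_trees = 5000L, learning_rate = 0.001,
                         max_depth = 3L, min_leaf = 5L, n_folds = 5L,
                         seed = 1L) {
  ctl <- list(n_trees = as.integer(n_trees), learning_rate = learning_rate,
              max_depth = as.integer(max_depth), min_leaf = as.integer(min_leaf),
              n_folds = as.integer(n_folds), seed = as.integer(seed))
  if (ctl$n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (!is.finite(ctl$learning_rate) || ctl$learning_rate <= 0 ||
      ctl$learning_rate > 1) {
    stop("learning_rate must be in (0, 1]", call. = FALSE)
  }
  if (ctl$max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  if (ctl$min_leaf < 1) stop("min_leaf must be >= 1", call. = FALSE)
  if (ctl$n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  structure(ctl, class = "gbdt_control")
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.numeric(X)) stop("predictors must be numeric", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X
}

# Greedy best split by squared-error reduction.  Candidate thresholds sit
# at midpoints of consecutive distinct sorted values; ties break to the
# lowest feature index, then the lowest threshold (strict > comparisons
# and which.max's first-hit rule).
best_split <- function(X, y, rows, min_leaf) {
  n <- length(rows)
  yr <- y[rows]
  best <- NULL
  best_imp <- 1e-12
  for (f in seq_len(ncol(X))) {
    x <- X[rows, f]
    o <- order(x)
    xs <- x[o]
    cy <- cumsum(yr[o])
    tot <- cy[n]
    i <- seq_len(n - 1L)
    ok <- (xs[i] < xs[i + 1L]) & (i >= min_leaf) & ((n - i) >= min_leaf)
    if (!any(ok)) next
    imp <- cy[i]^2 / i + (tot - cy[i])^2 / (n - i) - tot^2 / n
    imp[!ok] <- -Inf
    b <- which.max(imp)
    if (imp[b] > best_imp) {
      best_imp <- imp[b]
      best <- list(feature = f, threshold = (xs[b] + xs[b + 1L]) / 2,
                   improvement = imp[b])
    }
  }
  best
}

#' Fit a single CART regression tree
#'
#' Greedy recursive partitioning minimising squared error.  Each internal
#' node records the feature, midpoint threshold and squared-error
#' improvement of its split; each leaf holds the mean response of its
#' rows.  Growth stops at `max_depth`, at `min_leaf`, or when no split
#' improves the fit (e.g. constant predictors), in which case the node
#' stays a leaf.
#'
#' @param X Numeric matrix or data frame of predictors.
#' @param y Numeric response.
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_leaf Minimum rows per leaf.
#' @return A `regression_tree` with parallel node vectors `feature`,
#'   `threshold`, `value`, `left`, `right`, `improvement`, `is_leaf`.
#' @export
fit_regression_tree <- function(X, y, max_depth = 3L, min_leaf = 5L) {
  X <- as_feature_matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("predictors and response must be finite", call. = FALSE)
  }
  feature <- integer(0); threshold <- numeric(0); value <- numeric(0)
  left <- integer(0); right <- integer(0); improvement <- numeric(0)
  is_leaf <- logical(0)
  build <- function(rows, depth) {
    id <- length(is_leaf) + 1L
    is_leaf[id] <<- TRUE
    feature[id] <<- NA_integer_; threshold[id] <<- NA_real_
    value[id] <<- mean(y[rows])
    left[id] <<- NA_integer_; right[id] <<- NA_integer_
    improvement[id] <<- 0
    if (depth >= max_depth || length(rows) < 2L * min_leaf) return(id)
    s <- best_split(X, y, rows, min_leaf)
    if (is.null(s)) return(id)
    is_leaf[id] <<- FALSE
    feature[id] <<- s$feature; threshold[id] <<- s$threshold
    improvement[id] <<- s$improvement
    go_left <- X[rows, s$feature] <= s$threshold
    l <- build(rows[go_left], depth + 1L)
    left[id] <<- l
    r <- build(rows[!go_left], depth + 1L)
    right[id] <<- r
    id
  }
  build(seq_along(y), 0L)
  structure(list(feature = feature, threshold = threshold, value = value,
                 left = left, right = right, improvement = improvement,
                 is_leaf = is_leaf, feature_names = colnames(X)),
            class = "regression_tree")
}

#' Predict from a single regression tree
#'
#' @param tree A `regression_tree`.
#' @param X Predictor matrix/data frame with the training columns.
#' @return Numeric predictions, one per row.
#' @export
predict_regression_tree <- function(tree, X) {
  X <- as_feature_matrix(X)
  node <- rep(1L, nrow(X))
  for (id in seq_along(tree$is_leaf)) {
    if (tree$is_leaf[id]) next
    at <- which(node == id)
    if (!length(at)) next
    goL <- X[at, tree$feature[id]] <= tree$threshold[id]
    node[at[goL]] <- tree$left[id]
    node[at[!goL]] <- tree$right[id]
  }
  tree$value[node]
}

#' Fit a gradient-boosted regression-tree model
#'
#' Stagewise least-squares boosting: the model starts from the constant
#' `f_0 = mean(y)` (the squared-loss minimiser); each iteration fits a
#' CART tree to the current residuals (the negative gradient of squared
#' loss), whose leaf means are the closed-form line-search step, and adds
#' it scaled by the learning rate:
#' `f_m(x) = f_{m-1}(x) + xi * h_m(x)`.  The training mean-squared error
#' is recorded per iteration and is mathematically non-increasing for
#' `0 < xi <= 1`.  Split improvements are accumulated per feature for
#' relative-importance reporting.
#'
#' @param X Numeric predictor matrix or data frame (named columns).
#' @param y Numeric response.
#' @param control A [gbdt_control()].
#' @return A `gbdt_model`: `f0`, `trees`, `learning_rate`, `train_mse`
#'   (per-iteration trajectory), `raw_importance`, `feature_names`, `n`.
#' @export
#' @examples
#' X <- data.frame(x1 = runif(50), x2 = runif(50))
#' m <- fit_gbdt(X, 2 * X$x1, gbdt_control(n_trees = 50, learning_rate = 0.3))
#' cor(predict(m, X), 2 * X$x1)
fit_gbdt <- function(X, y, control = gbdt_control()) {
  X <- as_feature_matrix(X)
  if (nrow(X) != length(y)) stop("X and y sizes differ", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("predictors and response must be finite", call. = FALSE)
  }
  n <- nrow(X)
  f0 <- mean(y)
  pred <- rep(f0, n)
  M <- control$n_trees
  xi <- control$learning_rate
  trees <- vector("list", M)
  train_mse <- numeric(M)
  raw_imp <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (m in seq_len(M)) {
    r <- y - pred
    tr <- fit_regression_tree(X, r, max_depth = control$max_depth,
                              min_leaf = control$min_leaf)
    pred <- pred + xi * predict_regression_tree(tr, X)
    trees[[m]] <- tr
    train_mse[m] <- mean((y - pred)^2)
    sp <- !tr$is_leaf
    if (any(sp)) {
      agg <- tapply(tr$improvement[sp], tr$feature[sp], sum)
      ii <- as.integer(names(agg))
      raw_imp[ii] <- raw_imp[ii] + as.vector(agg)
    }
  }
  structure(list(f0 = f0, trees = trees, learning_rate = xi,
                 control = control, feature_names = colnames(X),
                 train_mse = train_mse, raw_importance = raw_imp, n = n),
            class = "gbdt_model")
}

#' @export
print.gbdt_model <- function(x, ...) {
  cat(sprintf("gbdt_model: %d trees, learning rate %g, depth <= %d, %d features, n = %d\n",
              length(x$trees), x$learning_rate, x$control$max_depth,
              length(x$feature_names), x$n))
  cat(sprintf("  training MSE: %.4g (first) -> %.4g (last)\n",
              x$train_mse[1], x$train_mse[length(x$train_mse)]))
  invisible(x)
}

#' Predict from a boosted model
#'
#' Evaluates the additive composition `f(x) = f_0 + xi * sum_m h_m(x)`.
#'
#' @param object A `gbdt_model`.
#' @param newdata Predictor matrix/data frame containing all training
#'   features (by name).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.gbdt_model <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(X))
  if (length(missing)) {
    stop("newdata is missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- X[, object$feature_names, drop = FALSE]
  out <- rep(object$f0, nrow(X))
  xi <- object$learning_rate
  for (tr in object$trees) {
    out <- out + xi * predict_regression_tree(tr, X)
  }
  out
}

#' k-fold cross-validation of the boosted model
#'
#' Shuffles rows with the control's seed, splits them into `n_folds`
#' contiguous folds, fits one model per held-out fold and reports the
#' validation R-squared `1 - SS_res / SS_tot` (SS_tot about the
#' validation-fold mean; may be negative for fits worse than the mean).
#'
#' @inheritParams fit_gbdt
#' @return A `gbdt_cv`: `fold_r2`, `mean_r2`, `n`, `control`.
#' @export
cross_validate_gbdt <- function(X, y, control = gbdt_control()) {
  X <- as_feature_matrix(X)
  n <- nrow(X)
  k <- control$n_folds
  if (k > n) stop("n_folds (", k, ") exceeds the number of rows (", n, ")",
                  call. = FALSE)
  set.seed(control$seed)
  idx <- sample.int(n)
  # contiguous blocks of the shuffled order
  sizes <- diff(floor(seq(0, n, length.out = k + 1)))
  fold_of <- integer(n)
  fold_of[idx] <- rep(seq_len(k), times = sizes)
  r2 <- numeric(k)
  for (f in seq_len(k)) {
    hold <- fold_of == f
    m <- fit_gbdt(X[!hold, , drop = FALSE], y[!hold], control)
    pv <- predict(m, X[hold, , drop = FALSE])
    yv <- y[hold]
    r2[f] <- 1 - sum((yv - pv)^2) / sum((yv - mean(yv))^2)
  }
  structure(list(fold_r2 = r2, mean_r2 = mean(r2), n = n, control = control),
            class = "gbdt_cv")
}

#' @export
print.gbdt_cv <- function(x, ...) {
  cat(sprintf("%d-fold CV: mean R2 = %.4f (folds: %s)\n",
              length(x$fold_r2), x$mean_r2,
              paste(sprintf("%.3f", x$fold_r2), collapse = ", ")))
  invisible(x)
}

#' Relative feature importance of a boosted model
#'
#' Attributes each split's squared-error improvement to its feature,
#' sums across all trees, and normalises to percentages summing to 100.
#' A model with no splits at all returns zeros with a warning.
#'
#' @param model A `gbdt_model`.
#' @return Data frame `feature`, `raw_improvement`, `importance_pct`,
#'   sorted by descending importance.
#' @export
feature_importance <- function(model) {
  raw <- model$raw_importance
  if (sum(raw) <= 0) {
    warning("model contains no splits; importance is uniformly zero",
            call. = FALSE)
    pct <- raw * 0
  } else {
    pct <- 100 * raw / sum(raw)
  }
  out <- data.frame(feature = names(raw), raw_improvement = unname(raw),
                    importance_pct = unname(pct), stringsAsFactors = FALSE)
  out <- out[order(-out$importance_pct, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Serialise / restore a boosted model as JSON
#'
#' The JSON document stores `f0`, `learning_rate`, `feature_names` and
#' every tree's parallel node arrays (`feature`, `threshold`, `value`,
#' `left`, `right`, `improvement`, `is_leaf`); leaves carry null
#' feature/threshold.
#'
#' @param model A `gbdt_model`.
#' @param path File path for the JSON document.
#' @return `write_gbdt_json()` returns `path` invisibly;
#'   `read_gbdt_json()` returns a `gbdt_model` usable with `predict()`.
#' @export
write_gbdt_json <- function(model, path) {
  doc <- list(
    f0 = model$f0,
    learning_rate = model$learning_rate,
    feature_names = model$feature_names,
    n = model$n,
    control = unclass(model$control),
    raw_importance = as.list(model$raw_importance),
    trees = lapply(model$trees, function(tr) {
      tr[c("feature", "threshold", "value", "left", "right",
           "improvement", "is_leaf")]
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_gbdt_json
#' @export
read_gbdt_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  nv <- function(v, cast) {
    cast(unlist(lapply(v, function(e) if (is.null(e)) NA else e)))
  }
  fix_tree <- function(tr) {
    structure(list(feature = nv(tr$feature, as.integer),
                   threshold = nv(tr$threshold, as.numeric),
                   value = nv(tr$value, as.numeric),
                   left = nv(tr$left, as.integer),
                   right = nv(tr$right, as.integer),
                   improvement = nv(tr$improvement, as.numeric),
                   is_leaf = nv(tr$is_leaf, as.logical)),
              class = "regression_tree")
  }
  structure(list(f0 = doc$f0,
                 trees = lapply(doc$trees, fix_tree),
                 learning_rate = doc$learning_rate,
                 control = do.call(gbdt_control, doc$control),
                 feature_names = unlist(doc$feature_names),
                 train_mse = numeric(0),
                 raw_importance = unlist(doc$raw_importance),
                 n = doc$n),
            class = "gbdt_model")
}
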