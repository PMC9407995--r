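#' Partial-dependence curve of one feature
#'
#' For each grid value `v` inside a quantile-clipped range of the
#' observed feature, computes the average model prediction with that
#' feature clamped to `v` over all rows.  The grid is confined to the
#' 1st--99th percentile by default so sparsely observed tails do not
#' produce unreliable estimates; per-bin sample counts are attached and
#' used to down-weight low-density bins during smoothing.
#'
#' @param model A fitted `gbdt_model`.
#' @param X Predictor data frame/matrix the model was trained on (or a
#'   representative sample).
#' @param feature Feature name to vary.
#' @param n_grid Number of grid points (default 50).
#' @param quantile_range Two quantiles bounding the grid (default
#'   `c(0.01, 0.99)`).
#' @param span Loess span passed to [smooth_curve()].
#' @return A `pd_curve` data frame: `grid`, `raw`, `smoothed`, `density`,
#'   with the feature name as attribute.
#' @export
partial_dependence <- function(model, X, feature, n_grid = 50L,
                               quantile_range = c(0.01, 0.99), span = 0.5) {
  X <- as.data.frame(X)
  if (!feature %in% names(X)) {
    stop("feature '", feature, "' not found in the data", call. = FALSE)
  }
  x <- X[[feature]]
  qs <- stats::quantile(x, quantile_range, names = FALSE)
  if (qs[1] == qs[2]) {
    warning("feature '", feature, "' is constant over the quantile range; ",
            "returning a single-point curve", call. = FALSE)
    grid <- qs[1]
  } else {
    grid <- seq(qs[1], qs[2], length.out = n_grid)
  }
  n <- nrow(X)
  ng <- length(grid)
  Xr <- X[rep(seq_len(n), ng), , drop = FALSE]
  Xr[[feature]] <- rep(grid, each = n)
  pred <- predict(model, Xr)
  raw <- colMeans(matrix(pred, n, ng))
  # observed-sample density per grid bin (bins split at grid midpoints)
  if (ng > 1) {
    mids <- (grid[-1] + grid[-ng]) / 2
    density <- as.vector(table(cut(x, breaks = c(-Inf, mids, Inf))))
    smoothed <- smooth_curve(grid, raw, span = span, weights = 1 + density)
  } else {
    density <- n
    smoothed <- raw
  }
  structure(data.frame(grid = grid, raw = raw, smoothed = smoothed,
                       density = density),
            feature = feature, class = c("pd_curve", "data.frame"))
}

#' @export
plot.pd_curve <- function(x, ...) {
  graphics::plot(x$grid, x$raw, type = "l", col = "grey60",
                 xlab = attr(x, "feature"), ylab = "partial dependence", ...)
  graphics::lines(x$grid, x$smoothed, col = "blue", lwd = 2)
  invisible(x)
}

#' Smooth a partial-dependence curve
#'
#' Locally-weighted regression (loess, quadratic local fits) over the
#' grid, keeping the endpoints in the evaluation.  Weights (typically
#' per-bin sample counts) down-weight sparsely observed grid regions so
#' noisy tail estimates do not dominate the smooth.
#'
#' @param grid Strictly increasing grid values (>= 5 points).
#' @param values Raw curve values at the grid.
#' @param span Loess span in (0, 1].
#' @param weights Optional non-negative observation weights.
#' @return Numeric vector of smoothed values, same length as `grid`.
#' @export
smooth_curve <- function(grid, values, span = 0.5, weights = NULL) {
  if (!is.numeric(span) || length(span) != 1 || span <= 0 || span > 1) {
    stop("span must be in (0, 1]", call. = FALSE)
  }
  if (length(grid) < 5) {
    stop("at least 5 grid points are required for smoothing", call. = FALSE)
  }
  if (length(values) != length(grid)) {
    stop("grid and values lengths differ", call. = FALSE)
  }
  df <- data.frame(g = grid, v = values)
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  fit <- stats::loess(v ~ g, data = df, span = span, degree = 2,
                      weights = w, surface = "direct",
                      family = "gaussian")
  as.vector(stats::predict(fit, newdata = df))
}

#' Select key variables from an importance table
#'
#' Keeps variables whose relative importance strictly exceeds the cutoff
#' (default 7%), ordered by descending importance.
#'
#' @param importance Output of [feature_importance()] (or any data frame
#'   with `feature` and `importance_pct`), or a named numeric vector of
#'   percentages.
#' @param threshold_pct Strict lower cutoff in percent (default 7).
#' @return Data frame `feature`, `importance_pct`, descending.
#' @export
select_key_variables <- function(importance, threshold_pct = 7) {
  if (is.numeric(importance) && !is.null(names(importance))) {
    importance <- data.frame(feature = names(importance),
                             importance_pct = unname(importance),
                             stringsAsFactors = FALSE)
  }
  if (!all(c("feature", "importance_pct") %in% names(importance))) {
    stop("importance must have columns feature and importance_pct",
         call. = FALSE)
  }
  out <- importance[importance$importance_pct > threshold_pct,
                    c("feature", "importance_pct"), drop = FALSE]
  out <- out[order(-out$importance_pct, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares baseline
#'
#' Global linear fit of the response on all predictors via `stats::lm`,
#' reported as coefficients, intercept and R-squared.  Rank-deficient
#' predictor sets are rejected with the collinear columns named.
#'
#' @param X Predictor data frame/matrix; more rows than predictors.
#' @param y Numeric response.
#' @return An `ols_result`: `coefficients`, `intercept`, `r_squared`, `n`.
#' @export
ols_fit <- function(X, y) {
  df <- as.data.frame(X)
  if (nrow(df) <= ncol(df)) {
    stop("OLS needs more rows (", nrow(df), ") than predictors (",
         ncol(df), ")", call. = FALSE)
  }
  mm <- cbind(`(Intercept)` = 1, as.matrix(df))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("predictors are rank-deficient; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  d <- df
  d[[".response"]] <- y
  fit <- stats::lm(.response ~ ., data = d)
  cf <- stats::coef(fit)
  structure(list(coefficients = cf[-1], intercept = unname(cf[1]),
                 r_squared = summary(fit)$r.squared, n = nrow(df)),
            class = "ols_result")
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("OLS: %d predictors, n = %d, R2 = %.4f\n",
              length(x$coefficients), x$n, x$r_squared))
  invisible(x)
}

#' Compare the OLS baseline with the boosted model
#'
#' Reports the OLS in-sample R-squared and the boosted model's mean
#' cross-validated R-squared, fitted on the same table, and their
#' difference (positive when boosting explains more).
#'
#' @param ols An [ols_fit()] result.
#' @param gbdt_cv A [cross_validate_gbdt()] result on the same data.
#' @return A `model_comparison` list: `ols_r2`, `gbdt_cv_r2`,
#'   `difference`, `n`.
#' @export
compare_models <- function(ols, gbdt_cv) {
  if (!inherits(ols, "ols_result") || !inherits(gbdt_cv, "gbdt_cv")) {
    stop("compare_models() expects an ols_result and a gbdt_cv", call. = FALSE)
  }
  if (ols$n != gbdt_cv$n) {
    stop("models were fitted on tables of different sizes (", ols$n,
         " vs ", gbdt_cv$n, ")", call. = FALSE)
  }
  structure(list(ols_r2 = ols$r_squared, gbdt_cv_r2 = gbdt_cv$mean_r2,
                 difference = gbdt_cv$mean_r2 - ols$r_squared, n = ols$n),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("OLS R2 = %.4f vs GBDT CV R2 = %.4f (difference %+.4f, n = %d)\n",
              x$ols_r2, x$gbdt_cv_r2, x$difference, x$n))
  invisible(x)
}
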