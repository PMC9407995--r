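test_that("a single tree splits a step function at the step", {
  X <- data.frame(x = 1:6)
  y <- c(0, 0, 0, 1, 1, 1)
  tr <- fit_regression_tree(X, y, max_depth = 1, min_leaf = 1)
  expect_false(tr$is_leaf[1])
  expect_equal(tr$threshold[1], 3.5)
  expect_setequal(tr$value[tr$is_leaf], c(0, 1))
  expect_equal(predict_regression_tree(tr, X), y)
  # improvement equals the full SSE of the node
  expect_equal(tr$improvement[1], sum((y - mean(y))^2))
})

test_that("trees degenerate gracefully and ignore row order", {
  # constant response -> single leaf
  tr <- fit_regression_tree(data.frame(x = 1:10), rep(4, 10), min_leaf = 1)
  expect_true(all(tr$is_leaf))
  expect_equal(tr$value[1], 4)
  # constant predictors with varying response -> single leaf, no error
  tr2 <- fit_regression_tree(data.frame(x = rep(1, 10)), rnorm(10), min_leaf = 1)
  expect_true(all(tr2$is_leaf))
  # permuting rows changes nothing
  set.seed(5)
  X <- data.frame(a = runif(30), b = runif(30))
  y <- X$a * 2 + rnorm(30, 0, 0.1)
  perm <- sample(30)
  t1 <- fit_regression_tree(X, y, max_depth = 2, min_leaf = 3)
  t2 <- fit_regression_tree(X[perm, ], y[perm], max_depth = 2, min_leaf = 3)
  expect_equal(t1$threshold, t2$threshold)
  expect_equal(t1$feature, t2$feature)
  grid <- data.frame(a = seq(0, 1, 0.05), b = 0.5)
  expect_equal(predict_regression_tree(t1, grid),
               predict_regression_tree(t2, grid))
})

test_that("boosting composes f0 with shrunken trees and reduces loss monotonically", {
  set.seed(21)
  X <- data.frame(x1 = runif(80), x2 = runif(80))
  y <- 3 * sin(5 * X$x1) + rnorm(80, 0, 0.3)
  ctl <- gbdt_control(n_trees = 60, learning_rate = 0.2, max_depth = 2,
                      min_leaf = 5)
  m <- fit_gbdt(X, y, ctl)
  expect_true(all(diff(m$train_mse) <= 1e-12))
  # definition audit: prediction = f0 + xi * sum of tree outputs
  manual <- rep(m$f0, nrow(X))
  for (tr in m$trees) {
    manual <- manual + m$learning_rate * predict_regression_tree(tr, X)
  }
  expect_equal(predict(m, X), manual)
  # constant response: f0 = c and all trees trivial
  mc <- fit_gbdt(X, rep(2.5, 80), gbdt_control(n_trees = 3, learning_rate = 1))
  expect_equal(predict(mc, X), rep(2.5, 80))
})

test_that("one unshrunk boosting round equals CART on the centred response", {
  set.seed(31)
  X <- data.frame(a = runif(50), b = runif(50))
  y <- 4 * (X$a > 0.6) + rnorm(50, 0, 0.2)
  m <- fit_gbdt(X, y, gbdt_control(n_trees = 1, learning_rate = 1,
                                   max_depth = 3, min_leaf = 5))
  cart <- fit_regression_tree(X, y - mean(y), max_depth = 3, min_leaf = 5)
  expect_equal(predict(m, X),
               mean(y) + predict_regression_tree(cart, X))
})

test_that("unlimited depth with unit learning rate drives training error to zero", {
  set.seed(41)
  X <- data.frame(x = runif(40))  # distinct values
  y <- rnorm(40)
  m <- fit_gbdt(X, y, gbdt_control(n_trees = 25, learning_rate = 1,
                                   max_depth = 12, min_leaf = 1))
  expect_lt(m$train_mse[25], 1e-10)
})

test_that("prediction demands the training features by name", {
  set.seed(51)
  X <- data.frame(u = runif(30), v = runif(30))
  m <- fit_gbdt(X, X$u, gbdt_control(n_trees = 5, learning_rate = 0.5))
  expect_error(predict(m, data.frame(u = runif(5))), "v")
  expect_error(fit_gbdt(X, c(rep(1, 29), NA)), "finite")
})

test_that("relative importance sums to 100 and tracks the informative feature", {
  set.seed(61)
  X <- data.frame(x1 = runif(200), x2 = runif(200), x3 = runif(200),
                  x3dup = runif(200))
  y <- sin(6 * X$x1)
  m <- fit_gbdt(X, y, gbdt_control(n_trees = 80, learning_rate = 0.2))
  imp <- feature_importance(m)
  expect_equal(sum(imp$importance_pct), 100, tolerance = 1e-9)
  expect_equal(imp$feature[1], "x1")
  expect_gt(imp$importance_pct[imp$feature == "x1"], 95)
  expect_lt(imp$importance_pct[imp$feature == "x3dup"], 2)
  # no-split model warns and returns zeros
  m0 <- fit_gbdt(X, rep(1, 200), gbdt_control(n_trees = 2, learning_rate = 1))
  expect_warning(imp0 <- feature_importance(m0), "no splits")
  expect_true(all(imp0$importance_pct == 0))
})

test_that("predictions agree with an established boosting implementation", {
  set.seed(71)
  n <- 500
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n),
                  x4 = runif(n), x5 = runif(n))
  y <- sin(4 * X$x1) + 2 * (X$x2 > 0.5) + 0.5 * X$x3 + rnorm(n, 0, 0.2)
  ours <- fit_gbdt(X, y, gbdt_control(n_trees = 100, learning_rate = 0.1,
                                      max_depth = 3, min_leaf = 5))
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  ref <- xgboost::xgb.train(
    params = list(eta = 0.1, max_depth = 3, lambda = 0, alpha = 0, gamma = 0,
                  min_child_weight = 5, base_score = mean(y),
                  objective = "reg:squarederror", tree_method = "exact"),
    data = dtrain, nrounds = 100, verbose = 0)
  p_ours <- predict(ours, X)
  p_ref <- predict(ref, dtrain)
  expect_gt(cor(p_ours, p_ref)^2, 0.99)
})

test_that("cross-validation is seeded, honest and bounded by fold count", {
  set.seed(81)
  n <- 150
  X <- data.frame(x1 = runif(n), x2 = runif(n))
  y_lin <- 1 + 2 * X$x1
  ctl <- gbdt_control(n_trees = 150, learning_rate = 0.1, max_depth = 2,
                      min_leaf = 5, n_folds = 5, seed = 42)
  cv1 <- cross_validate_gbdt(X, y_lin, ctl)
  cv2 <- cross_validate_gbdt(X, y_lin, ctl)
  expect_identical(cv1$fold_r2, cv2$fold_r2)
  expect_length(cv1$fold_r2, 5)
  # noiseless structured signal is recovered well out of sample
  expect_gte(cv1$mean_r2, 0.9)
  # pure noise cannot be predicted
  y_noise <- rnorm(n)
  cv0 <- cross_validate_gbdt(X, y_noise, ctl)
  expect_lt(cv0$mean_r2, 0.2)
  expect_error(cross_validate_gbdt(X[1:3, ], y_lin[1:3], ctl), "n_folds")
})

test_that("JSON round-trip preserves the model exactly", {
  set.seed(91)
  X <- data.frame(a = runif(40), b = runif(40))
  m <- fit_gbdt(X, 2 * X$a + rnorm(40, 0, 0.1),
                gbdt_control(n_trees = 10, learning_rate = 0.3))
  path <- withr::local_tempfile(fileext = ".json")
  write_gbdt_json(m, path)
  m2 <- read_gbdt_json(path)
  expect_equal(predict(m2, X), predict(m, X))
  expect_equal(m2$f0, m$f0)
})

test_that("hyperparameter validation rejects out-of-range values", {
  expect_error(gbdt_control(n_trees = 0), "n_trees")
  expect_error(gbdt_control(learning_rate = 0), "learning_rate")
  expect_error(gbdt_control(learning_rate = 1.5), "learning_rate")
  expect_error(gbdt_control(n_folds = 1), "n_folds")
})
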