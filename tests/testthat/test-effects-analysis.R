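test_that("partial dependence is flat for ignored features and linear for linear ones", {
  set.seed(12)
  n <- 300
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  y <- 2 * X$x1
  m <- fit_gbdt(X, y, gbdt_control(n_trees = 200, learning_rate = 0.1,
                                   max_depth = 2, min_leaf = 5))
  # x3 carries no signal -> curve flat relative to the response range
  pd3 <- partial_dependence(m, X, "x3")
  expect_lt(diff(range(pd3$raw)), 0.01 * diff(range(y)))
  # PD of the linear driver recovers slope ~ 2 over the interior grid
  pd1 <- partial_dependence(m, X, "x1")
  slope <- coef(lm(raw ~ grid, data = as.data.frame(pd1)))[2]
  expect_equal(unname(slope), 2, tolerance = 0.15)
  expect_equal(nrow(pd1), 50)
  # grid respects the quantile clipping
  expect_gte(min(pd1$grid), quantile(X$x1, 0.01))
  expect_lte(max(pd1$grid), quantile(X$x1, 0.99))
  expect_error(partial_dependence(m, X, "zz"), "zz")
  # constant feature collapses to a single point with a warning
  Xc <- X
  Xc$x3 <- 1
  mc <- fit_gbdt(Xc, y, gbdt_control(n_trees = 10, learning_rate = 0.5))
  expect_warning(pdc <- partial_dependence(mc, Xc, "x3"), "constant")
  expect_equal(nrow(pdc), 1)
})

test_that("partial dependence of an additive model is unaffected by other features", {
  # additive ground truth: PD in x1 should not depend on x2's distribution
  set.seed(22)
  n <- 400
  mk <- function(shift) {
    X <- data.frame(x1 = runif(n), x2 = runif(n) + shift)
    list(X = X, y = pmin(X$x1, 0.5) * 10 + 3 * X$x2)
  }
  d1 <- mk(0)
  d2 <- mk(2)
  ctl <- gbdt_control(n_trees = 250, learning_rate = 0.1, max_depth = 3,
                      min_leaf = 5)
  m1 <- fit_gbdt(d1$X, d1$y, ctl)
  m2 <- fit_gbdt(d2$X, d2$y, ctl)
  g <- seq(0.1, 0.9, length.out = 20)
  pd_at <- function(m, X, g) {
    vapply(g, function(v) {
      Xv <- X
      Xv$x1 <- v
      mean(predict(m, Xv))
    }, numeric(1))
  }
  c1 <- pd_at(m1, d1$X, g)
  c2 <- pd_at(m2, d2$X, g)
  # same shape up to the additive offset from x2
  expect_lt(max(abs((c1 - mean(c1)) - (c2 - mean(c2)))), 0.5)
})

test_that("curve smoothing preserves smooth input and attenuates spikes", {
  g <- seq(0, 1, length.out = 50)
  lin <- 2 + 3 * g
  expect_equal(smooth_curve(g, lin), lin, tolerance = 1e-6)
  expect_length(smooth_curve(g, lin), 50)
  # single spike on a flat curve is attenuated below half its amplitude
  spiky <- rep(1, 50)
  spiky[25] <- 2
  sm <- smooth_curve(g, spiky)
  expect_lt(max(abs(sm - 1)), 0.5)
  expect_error(smooth_curve(g, lin, span = 0), "span")
  expect_error(smooth_curve(g, lin, span = 1.5), "span")
  expect_error(smooth_curve(g[1:4], lin[1:4]), "5 grid points")
})

test_that("key-variable selection applies a strict threshold in descending order", {
  imp <- data.frame(feature = c("a", "b", "c"),
                    importance_pct = c(40, 50, 10))
  k <- select_key_variables(imp, 7)
  expect_equal(k$feature, c("b", "a", "c"))
  # strict >: a variable exactly at the threshold is excluded
  imp2 <- data.frame(feature = c("a", "b"), importance_pct = c(93, 7))
  expect_equal(select_key_variables(imp2, 7)$feature, "a")
  # idempotent and input-order independent
  k2 <- select_key_variables(imp[c(3, 1, 2), ], 7)
  expect_equal(k, k2)
  expect_equal(select_key_variables(k, 7), k)
  # a Table-3-shaped profile with five values above 7% yields five keys
  imp3 <- data.frame(
    feature = c("PD", "IFA", "PI", "GDP", "RCG", "SAD", "P_NDVI", "LUM",
                "PC", "PCAR", "RI", "PR", "PFBR", "RD", "PTN"),
    importance_pct = c(20.86, 17.35, 14.43, 13.75, 12.87, 4.18, 4.74, 3.42,
                       2.32, 1.88, 1.88, 1.32, 0.51, 0.45, 0.04))
  expect_equal(select_key_variables(imp3, 7)$feature,
               c("PD", "IFA", "PI", "GDP", "RCG"))
})

test_that("OLS matches the textbook normal-equations solution", {
  set.seed(33)
  X <- data.frame(a = rnorm(10), b = rnorm(10), c = rnorm(10))
  beta <- c(1.5, -2, 0.5)
  y <- 2 + as.matrix(X) %*% beta + rnorm(10, 0, 0.3)
  fit <- ols_fit(X, as.vector(y))
  M <- cbind(1, as.matrix(X))
  beta_hat <- solve(t(M) %*% M, t(M) %*% y)
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               as.vector(beta_hat), tolerance = 1e-8)
  # exact linear data -> R2 = 1 and coefficients recovered (lm warns
  # about the perfect fit, which is precisely the point here)
  y0 <- 2 + as.matrix(X) %*% beta
  fit0 <- suppressWarnings(ols_fit(X, as.vector(y0)))
  expect_equal(fit0$r_squared, 1)
  expect_equal(unname(fit0$coefficients), beta)
  # response orthogonal to the predictors -> R2 ~ 0
  set.seed(34)
  Xn <- data.frame(a = rnorm(200), b = rnorm(200))
  fitn <- ols_fit(Xn, rnorm(200))
  expect_lt(fitn$r_squared, 0.1)
  # collinear columns are named
  Xc <- data.frame(a = rnorm(20))
  Xc$b <- 2 * Xc$a
  expect_error(ols_fit(Xc, rnorm(20)), "b")
})

test_that("OLS R2 never decreases when a predictor is added", {
  set.seed(44)
  X <- data.frame(a = rnorm(50), b = rnorm(50), c = rnorm(50))
  y <- X$a + rnorm(50)
  r2 <- vapply(1:3, function(k) ols_fit(X[, 1:k, drop = FALSE], y)$r_squared,
               numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("model comparison favours boosting on nonlinear data only", {
  set.seed(55)
  n <- 300
  X <- data.frame(x1 = runif(n), x2 = runif(n), x3 = runif(n))
  ctl <- gbdt_control(n_trees = 250, learning_rate = 0.1, max_depth = 3,
                      min_leaf = 5, seed = 9)
  # strongly nonlinear generative signal
  y_nl <- 10 * pmin(X$x1, 0.4) + 5 * sin(8 * X$x2) + rnorm(n, 0, 0.3)
  cmp_nl <- compare_models(ols_fit(X, y_nl), cross_validate_gbdt(X, y_nl, ctl))
  expect_gt(cmp_nl$difference, 0)
  # purely linear generative signal: both models close
  y_lin <- 2 * X$x1 - X$x2 + rnorm(n, 0, 0.3)
  cmp_lin <- compare_models(ols_fit(X, y_lin),
                            cross_validate_gbdt(X, y_lin, ctl))
  expect_lt(abs(cmp_lin$difference), 0.1)
  # identical inputs give identical deterministic reports
  cmp_lin2 <- compare_models(ols_fit(X, y_lin),
                             cross_validate_gbdt(X, y_lin, ctl))
  expect_identical(cmp_lin, cmp_lin2)
  # mismatched table sizes are rejected
  expect_error(compare_models(ols_fit(X[1:100, ], y_lin[1:100]),
                              cross_validate_gbdt(X, y_lin, ctl)),
               "different sizes")
})
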