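test_that("one informative direction is captured by a single component", {
  set.seed(11)
  t1 <- stats::rnorm(20)
  X <- outer(t1, stats::rnorm(8))
  y <- drop(X %*% stats::rnorm(8))
  fit <- plsr_fit(X, y, 1)
  expect_lt(max(abs(plsr_predict(fit, X) - y)) / stats::sd(y), 1e-8)
})

test_that("full-rank PLSR coincides with ordinary least squares", {
  set.seed(12)
  for (i in 1:5) {
    X <- matrix(stats::rnorm(20 * 10), 20, 10)
    y <- drop(X %*% stats::rnorm(10)) + stats::rnorm(20)
    fit <- plsr_fit(X, y, 10)
    ols <- stats::lm.fit(cbind(1, X), y)
    pred_ols <- drop(cbind(1, X) %*% ols$coefficients)
    expect_lt(max(abs(plsr_predict(fit, X) - pred_ols)) / stats::sd(y), 1e-6)
  }
})

test_that("NIPALS scores are mutually orthogonal", {
  set.seed(13)
  X <- matrix(stats::rnorm(30 * 15), 30, 15)
  y <- stats::rnorm(30)
  fit <- plsr_fit(X, y, 5)
  G <- crossprod(fit$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
})

test_that("prediction is the documented affine map with exact centering", {
  set.seed(14)
  X <- matrix(stats::rnorm(25 * 6), 25, 6)
  y <- stats::rnorm(25, 120, 15)
  fit <- plsr_fit(X, y, 3)
  # calibration rows reproduce the fitted values through X B + B0
  manual <- drop(X %*% fit$coefficients) + fit$intercept
  expect_equal(plsr_predict(fit, X), manual)
  # the mean calibration spectrum maps to the mean concentration
  expect_equal(plsr_predict(fit, colMeans(X)), mean(y), tolerance = 1e-10)
  # an appended constant column changes nothing after centering
  fit2 <- plsr_fit(cbind(X, 5), y, 3)
  expect_equal(plsr_predict(fit2, cbind(X, 5)), plsr_predict(fit, X),
               tolerance = 1e-8)
  expect_error(plsr_predict(fit, X[, 1:4]), "column")
  expect_error(plsr_fit(X, rep(1, 25), 2), "constant")
  expect_error(plsr_fit(X, y, 25), "n_components")
})

test_that("agrees with an independent PLS implementation", {
  set.seed(42)
  X <- matrix(stats::rnorm(30 * 12), 30, 12,
              dimnames = list(NULL, paste0("w", 1:12)))
  y <- drop(X %*% stats::rnorm(12)) + stats::rnorm(30, sd = 0.3)
  fit <- plsr_fit(X, y, 3)
  mo <- mixOmics::pls(X, y, ncomp = 3, mode = "regression", scale = FALSE)
  pm <- stats::predict(mo, X)$predict[, 1, 3]
  expect_lt(max(abs(plsr_predict(fit, X) - pm)), 1e-8)
})

test_that("metrics match hand computations and training optimality", {
  m <- compute_metrics(c(1, 2, 3), c(2, 3, 4))
  expect_equal(m$rmse, 1)
  expect_equal(m$r2, 1 - 3 / 2)
  perfect <- compute_metrics(c(5, 7, 9), c(5, 7, 9), role = "calibration")
  expect_identical(perfect$r2, 1)
  expect_identical(perfect$rmse, 0)
  expect_error(compute_metrics(c(1, 1), c(1, 2)), "constant")
  expect_error(compute_metrics(1:3, 1:2), "length")
  # shuffling predictions cannot beat the fitted model on its own data
  set.seed(15)
  X <- matrix(stats::rnorm(20 * 5), 20, 5)
  y <- drop(X %*% stats::rnorm(5)) + stats::rnorm(20, sd = 0.1)
  fit <- plsr_fit(X, y, 3)
  yhat <- plsr_predict(fit, X)
  r2_fit <- compute_metrics(y, yhat)$r2
  for (i in 1:5)
    expect_lte(compute_metrics(y, sample(yhat))$r2, r2_fit)
})

test_that("cross-validation picks honest component counts", {
  set.seed(16)
  t1 <- stats::rnorm(40)
  X <- outer(t1, stats::rnorm(12)) # exactly one factor
  y <- 3 * t1 + 100
  sel <- select_components(X, y, folds = 5, max_k = 6, seed = 2)
  expect_identical(sel$k, 1L)
  # pure-noise response: no spurious gain over the mean-only predictor
  Xn <- matrix(stats::rnorm(40 * 12), 40, 12)
  yn <- stats::rnorm(40)
  seln <- select_components(Xn, yn, folds = 5, max_k = 6, seed = 2)
  rmse_mean <- sqrt(mean((yn - mean(yn))^2))
  expect_gte(seln$cv_rmse[seln$k], 0.9 * rmse_mean)
  # deterministic given the fold seed
  expect_identical(seln, select_components(Xn, yn, folds = 5, max_k = 6,
                                           seed = 2))
  expect_error(select_components(Xn, yn, folds = 1), "folds")
})
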