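# NIPALS PLS1 core: mean-centered X and y, returns weights/scores/loadings
# and the coefficient path (one column of B per component count).
# With strict = FALSE a rank-deficient request does not error: extraction
# stops early and the coefficient path is padded with its last column
# (extra components add nothing), which cross-validation relies on.
.nipals_pls1 <- function(X, y, ncomp, strict = TRUE) {
  n <- nrow(X); p <- ncol(X)
  xmean <- colMeans(X); ymean <- mean(y)
  Xc <- sweep(X, 2, xmean)
  yc <- y - ymean
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  qv <- numeric(ncomp)
  scale0 <- sqrt(sum(Xc^2) * sum(yc^2)) + .Machine$double.eps
  reached <- 0L
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * scale0) {
      if (strict)
        stop(sprintf("rank-deficient request: only %d informative components",
                     k - 1))
      break
    }
    w <- w / nw
    tk <- drop(Xc %*% w)
    tt <- sum(tk^2)
    if (tt < 1e-24 * scale0) {
      if (strict)
        stop(sprintf("rank-deficient request: only %d informative components",
                     k - 1))
      break
    }
    pk <- drop(crossprod(Xc, tk)) / tt
    qk <- sum(yc * tk) / tt
    Xc <- Xc - tcrossprod(tk, pk)
    yc <- yc - qk * tk
    W[, k] <- w; P[, k] <- pk; Tm[, k] <- tk; qv[k] <- qk
    reached <- k
  }
  # coefficient path: B_k = W_k (P_k' W_k)^{-1} q_k for k = 1..reached
  Bpath <- matrix(0, p, ncomp)
  for (k in seq_len(reached)) {
    Wk <- W[, seq_len(k), drop = FALSE]
    Pk <- P[, seq_len(k), drop = FALSE]
    Bpath[, k] <- drop(Wk %*% solve(crossprod(Pk, Wk), qv[seq_len(k)]))
  }
  if (reached < ncomp && reached > 0L)
    for (k in (reached + 1L):ncomp) Bpath[, k] <- Bpath[, reached]
  list(weights = W, loadings = P, scores = Tm, q = qv, coef_path = Bpath,
       x_mean = xmean, y_mean = ymean, n_reached = reached)
}

#' Fit a partial least squares regression model
#'
#' PLS1 by the NIPALS algorithm on mean-centered data (no variance
#' scaling), the standard chemometric calibration for high-dimensional,
#' collinear spectra. Deterministic: there is no random initialization.
#' At full rank the fit coincides with ordinary least squares.
#'
#' @param X Numeric matrix, samples x wavelengths.
#' @param y Response vector (concentrations, g/L), non-constant.
#' @param n_components Number of latent components, between 1 and
#'   `min(nrow(X) - 1, ncol(X))`.
#' @return An object of class `plsr_model` with the coefficient vector
#'   `coefficients` (B), `intercept` (B0), centering offsets, scores,
#'   loadings and weights, such that prediction = X B + B0.
#' @export
plsr_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("row count of X must match length of y")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (stats::var(y) == 0) stop("constant response: nothing to calibrate")
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1 || n_components > kmax)
    stop(sprintf("n_components must lie in [1, %d]", kmax))
  fit <- .nipals_pls1(X, y, n_components)
  B <- fit$coef_path[, n_components]
  B0 <- fit$y_mean - sum(fit$x_mean * B)
  structure(list(n_components = n_components, coefficients = B,
                 intercept = B0, x_mean = fit$x_mean, y_mean = fit$y_mean,
                 scores = fit$scores, loadings = fit$loadings,
                 weights = fit$weights, q = fit$q,
                 coef_path = fit$coef_path),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d components, %d wavelengths\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Predict concentrations from a fitted PLSR model
#'
#' Affine map `X B + B0`. The calibration mean spectrum maps to the
#' calibration mean concentration by construction.
#'
#' @param model A [plsr_fit()] model.
#' @param X_new Matrix (or vector) with the model's number of wavelengths.
#' @return Vector of predicted concentrations, g/L.
#' @export
plsr_predict <- function(model, X_new) {
  stopifnot(inherits(model, "plsr_model"))
  if (is.vector(X_new)) X_new <- matrix(X_new, nrow = 1)
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$coefficients))
    stop("X_new column count does not match the model")
  drop(X_new %*% model$coefficients) + model$intercept
}

#' Calibration / prediction performance metrics
#'
#' Determination coefficient `R^2 = 1 - SS_res / SS_tot` and root mean
#' square error, the standard figures of merit of multivariate calibration
#' (RMSEC on the calibration set, RMSEP on the prediction set).
#'
#' @param y_true Reference values (non-constant, length >= 2).
#' @param y_pred Predicted values.
#' @param role Label, e.g. `"calibration"` or `"prediction"`.
#' @return List with `role`, `r2`, `rmse` and `n`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(2, 3, 4))$rmse # 1
#' @export
compute_metrics <- function(y_true, y_pred, role = "prediction") {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least two observations")
  sstot <- sum((y_true - mean(y_true))^2)
  if (sstot == 0) stop("constant reference values: R^2 undefined")
  ssres <- sum((y_true - y_pred)^2)
  list(role = role, r2 = 1 - ssres / sstot,
       rmse = sqrt(mean((y_true - y_pred)^2)), n = length(y_true))
}

#' Choose the number of latent components by cross-validation
#'
#' k-fold cross-validation on the calibration set; returns the component
#' count minimizing the cross-validated RMSE, preferring the smaller count
#' on ties (within a 1e-10 relative tolerance). Fold assignment is
#' deterministic given the seed.
#'
#' @param X,y Calibration data as in [plsr_fit()].
#' @param folds Number of folds (>= 2, default 5).
#' @param max_k Largest component count to consider (default: up to 10,
#'   limited by the fold sizes and the number of wavelengths).
#' @param seed Seed for the fold assignment.
#' @return List with `k` (chosen count) and `cv_rmse` (vector over 1:max_k).
#' @export
select_components <- function(X, y, folds = 5, max_k = NULL, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (folds < 2 || folds > n) stop("folds must lie in [2, nrow(X)]")
  kcap <- min(n - ceiling(n / folds) - 1L, ncol(X))
  if (is.null(max_k)) max_k <- min(10L, kcap)
  if (max_k < 1 || max_k > kcap)
    stop(sprintf("max_k must lie in [1, %d]", kcap))
  fold_id <- .with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
  sq_err <- matrix(NA_real_, n, max_k)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit <- .nipals_pls1(X[!test, , drop = FALSE], y[!test], max_k,
                        strict = FALSE)
    Xt <- sweep(X[test, , drop = FALSE], 2, fit$x_mean)
    for (k in seq_len(max_k)) {
      pred <- drop(Xt %*% fit$coef_path[, k]) + fit$y_mean
      sq_err[test, k] <- (y[test] - pred)^2
    }
  }
  cv_rmse <- sqrt(colMeans(sq_err))
  best <- which(cv_rmse <= min(cv_rmse) * (1 + 1e-10))[1]
  list(k = as.integer(best), cv_rmse = cv_rmse)
}
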