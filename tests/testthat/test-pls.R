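random_instance <- function(seed, n, p) {
  set.seed(seed)
  list(X = matrix(rnorm(n * p), n, p), y = rnorm(n))
}

test_that("kernel PLS matches the NIPALS reference implementation", {
  cases <- list(c(12, 8), c(20, 30), c(15, 5))
  for (i in seq_along(cases)) {
    n <- cases[[i]][1]; p <- cases[[i]][2]
    inst <- random_instance(200 + i, n, p)
    colnames(inst$X) <- paste0("v", seq_len(p))
    a_max <- min(4, n - 1, p)
    ref <- mixOmics::pls(inst$X, inst$y, ncomp = a_max, scale = FALSE,
                         mode = "regression")
    ref_pred <- predict(ref, inst$X)
    for (a in seq_len(a_max)) {
      fit <- fit_kernel_pls(inst$X, inst$y, ncomp = a)
      expect_equal(fit$fitted, unname(ref_pred$predict[, 1, a]),
                   tolerance = 1e-8)
      # scores and loadings agree up to component sign
      sgn <- sign(diag(crossprod(fit$scores,
                                 ref$variates$X[, seq_len(a), drop = FALSE])))
      expect_equal(unname(fit$scores %*% diag(sgn, a)),
                   unname(ref$variates$X[, seq_len(a), drop = FALSE]),
                   tolerance = 1e-8)
      expect_equal(unname(fit$weights %*% diag(sgn, a)),
                   unname(ref$loadings$X[, seq_len(a), drop = FALSE]),
                   tolerance = 1e-8)
    }
  }
})

test_that("full-rank PLS equals ordinary least squares", {
  for (seed in 1:3) {
    inst <- random_instance(300 + seed, 14, 6)
    fit <- fit_kernel_pls(inst$X, inst$y, ncomp = 6)
    Xc <- scale(inst$X, scale = FALSE)
    ols <- lm.fit(Xc, inst$y - mean(inst$y))$coefficients
    expect_equal(unname(fit$coefficients), unname(ols), tolerance = 1e-8)
    expect_equal(fit$fitted,
                 drop(Xc %*% ols) + mean(inst$y), tolerance = 1e-8)
  }
})

test_that("a single component suffices for rank-one data", {
  set.seed(42)
  t1 <- rnorm(10)
  X <- tcrossprod(t1, rnorm(6))
  y <- drop(X %*% c(1, 0, 0, 0, 0, 0))
  fit <- fit_kernel_pls(X, y, ncomp = 1)
  expect_equal(fit$fitted, y, tolerance = 1e-10)
  expect_equal(sum(fit$explained_y), 100, tolerance = 1e-8)
})

test_that("scores are orthogonal and centering shifts commute", {
  inst <- random_instance(77, 16, 10)
  fit <- fit_kernel_pls(inst$X, inst$y, ncomp = 5)
  G <- crossprod(fit$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  # adding a constant to y shifts every prediction by that constant
  fit2 <- fit_kernel_pls(inst$X, inst$y + 5, ncomp = 5)
  expect_equal(fit2$fitted, fit$fitted + 5, tolerance = 1e-10)
})

test_that("explained variance accounting is complete and monotone", {
  inst <- random_instance(88, 12, 8)
  a_full <- 8
  fit <- fit_kernel_pls(inst$X, inst$y, ncomp = a_full)
  ev <- explained_variance(fit)
  expect_equal(ev$cum_explained_x[fit$ncomp], 100, tolerance = 1e-6)
  expect_true(all(diff(ev$cum_explained_x) >= -1e-10))
  expect_true(all(ev$cum_explained_x <= 100 + 1e-8))
  expect_true(all(ev$cum_explained_y <= 100 + 1e-8))
})

test_that("prediction applies stored centering consistently", {
  inst <- random_instance(55, 12, 7)
  fit <- fit_kernel_pls(inst$X, inst$y, ncomp = 3)
  pred <- predict(fit, inst$X)
  expect_equal(pred$.pred_log10, fit$fitted, tolerance = 1e-10)
  # the column-mean point predicts the response mean
  centroid <- matrix(fit$column_means, 1)
  expect_equal(predict(fit, centroid)$.pred_log10, fit$y_mean,
               tolerance = 1e-10)
  dup <- inst$X[c(2, 2), , drop = FALSE]
  pd <- predict(fit, dup)
  expect_equal(pd$.pred_log10[1], pd$.pred_log10[2])
  expect_error(predict(fit, inst$X[, 1:3]), "expected 7")
})

test_that("error metrics match their closed forms", {
  expect_equal(rmse_of(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  expect_equal(rmse_of(1:5, 1:5), 0)
  y <- rnorm(10)
  expect_equal(bias_of(y, y + 0.08), 0.08, tolerance = 1e-12)
  expect_equal(bias_of(y, y), 0)
  expect_equal(r2_pred_of(y, y + 0.08), 1, tolerance = 1e-12)
  set.seed(1)
  yh <- y + rnorm(10)
  expect_equal(r2_pred_of(y, yh), pearson_r(y, yh)^2, tolerance = 1e-12)
  expect_equal(r2_pred_of(y, yh, method = "press"),
               1 - sum((y - yh)^2) / sum((y - mean(y))^2), tolerance = 1e-12)
  expect_error(rmse_of(numeric(0), numeric(0)), "empty")
})

test_that("cross-validation recovers the latent dimension of noiseless data", {
  set.seed(5)
  T2 <- matrix(rnorm(20 * 2), 20, 2)
  X <- T2 %*% t(matrix(rnorm(15 * 2), 15, 2))
  y <- drop(T2 %*% c(1, -0.5))
  cv <- suppressWarnings(
    cross_validate_pls(X, y, a_max = 5, folds = venetian_blinds(20, 4)))
  expect_lt(cv$rmsecv$rmsecv[2], 1e-8)
  expect_equal(cv$ncomp, 2L)
})

test_that("cross-validation picks three components for three latent factors", {
  for (seed in c(42, 13)) {
    set.seed(seed)
    n <- 30; p <- 50
    Tm <- scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)
    X <- Tm %*% t(matrix(rnorm(p * 3), p, 3)) +
      matrix(rnorm(n * p, sd = 0.05), n, p)
    y <- drop(Tm %*% c(1, 0.6, 0.4)) + rnorm(n, sd = 0.05)
    cv <- cross_validate_pls(X, y, a_max = 8, folds = venetian_blinds(n, 5))
    expect_equal(cv$ncomp, 3L)
    # past the true dimension, RMSECV does not keep improving materially
    expect_gt(min(cv$rmsecv$rmsecv[4:8]), cv$rmsecv$rmsecv[3] * 0.98)
  }
})

test_that("cross-validation equals a fold-by-fold refit oracle", {
  inst <- random_instance(66, 18, 9)
  folds <- venetian_blinds(18, 3)
  cv <- cross_validate_pls(inst$X, inst$y, a_max = 4, folds = folds)
  expect_equal(cv$rmsecv$rmsecv, cv_oracle(inst$X, inst$y, 4, folds),
               tolerance = 1e-10)
})

test_that("degenerate requests are rejected", {
  inst <- random_instance(9, 8, 5)
  expect_error(fit_kernel_pls(inst$X, inst$y, ncomp = 9), "ncomp")
  expect_error(cross_validate_pls(inst$X, inst$y, a_max = 6,
                                  folds = venetian_blinds(8, 2)),
               "fewer than")
})
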