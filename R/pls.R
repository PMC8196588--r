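#' Single-response kernel partial least squares regression
#'
#' Fits a PLS1 model by sequential extraction of latent variables: for each
#' component the weight vector is the (normalized) covariance `X'y`, scores
#' are `t = X w`, loadings `p = X't / t't`, y-loading `q = y't / t't`, and
#' `X` is deflated by the rank-one score/loading product. For a single
#' response this produces exactly the weights, scores, loadings and
#' predictions of the covariance-deflating kernel algorithm and of NIPALS.
#' The overall regression vector is `B = W (P'W)^-1 q`, applied to
#' column-centered data.
#'
#' @param X Numeric matrix, samples in rows (raw; centered internally when
#'   `center = TRUE`).
#' @param y Numeric response vector (log10 tomatine, mg/kg DW).
#' @param ncomp Number of latent variables, `<= min(n - 1, p)`.
#' @param center Center `X` columns and `y` (default) and store the means
#'   for prediction. Set to `FALSE` only for pre-centered input (means are
#'   then recorded as zero).
#' @return Object of class `kernel_pls` with elements `ncomp`, `weights`
#'   (`p x A`), `loadings` (`p x A`), `y_loadings` (length `A`), `scores`
#'   (`n x A`), `coefficients` (length `p`, centered scale), `column_means`,
#'   `y_mean`, `wavenumbers` (from column names when numeric),
#'   `explained_x` and `explained_y` (percent variance per component) and
#'   `fitted` (training-scale fitted responses).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 12, 5)
#' y <- X %*% rnorm(5) + rnorm(12, sd = 0.01)
#' fit <- fit_kernel_pls(X, y, ncomp = 3)
#' glance(fit)
#' @export
fit_kernel_pls <- function(X, y, ncomp, center = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort("X and y disagree on sample count")
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    abort("ncomp must be between 1 and min(n - 1, p)")
  }
  if (center) {
    column_means <- colMeans(X)
    y_mean <- mean(y)
  } else {
    column_means <- numeric(p)
    y_mean <- 0
  }
  Xc <- sweep(X, 2, column_means)
  yc <- y - y_mean
  ssx <- sum(Xc^2)
  ssy <- sum(yc^2)

  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  explained_x <- numeric(ncomp)
  Xd <- Xc
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) {
      warn(sprintf("X'y vanished at component %d; stopping with %d", a, a - 1L))
      break
    }
    w <- w / nw
    t_a <- drop(Xd %*% w)
    tt <- sum(t_a^2)
    if (tt < 1e-28) {
      warn(sprintf("degenerate score at component %d; stopping with %d",
                   a, a - 1L))
      break
    }
    p_a <- drop(crossprod(Xd, t_a)) / tt
    q_a <- sum(yc * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    W[, a] <- w
    P[, a] <- p_a
    Tm[, a] <- t_a
    q[a] <- q_a
    explained_x[a] <- if (ssx > 0) 100 * tt * sum(p_a^2) / ssx else 0
    a_used <- a
  }
  if (a_used == 0L) abort("no latent variable could be extracted")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Tm <- Tm[, seq_len(a_used), drop = FALSE]
  q <- q[seq_len(a_used)]
  explained_x <- explained_x[seq_len(a_used)]

  B <- drop(W %*% solve(crossprod(P, W), q))
  # incremental Y-variance per component from cumulative fitted values
  rss <- vapply(seq_len(a_used), function(a) {
    sum((yc - drop(Tm[, seq_len(a), drop = FALSE] %*% q[seq_len(a)]))^2)
  }, numeric(1))
  explained_y <- if (ssy > 0) 100 * (c(ssy, rss[-a_used]) - rss) / ssy
                 else rep(0, a_used)

  wn <- suppressWarnings(as.numeric(colnames(X)))
  structure(
    list(
      ncomp = a_used,
      weights = W,
      loadings = P,
      y_loadings = q,
      scores = Tm,
      coefficients = B,
      column_means = column_means,
      y_mean = y_mean,
      wavenumbers = if (length(wn) == p && !anyNA(wn)) wn else NULL,
      explained_x = explained_x,
      explained_y = explained_y,
      fitted = drop(Xc %*% B) + y_mean,
      y = y,
      n = n,
      p = p
    ),
    class = "kernel_pls"
  )
}

#' @export
print.kernel_pls <- function(x, ...) {
  cat(sprintf("Kernel PLS (single response): %d latent variable(s), n = %d, p = %d\n",
              x$ncomp, x$n, x$p))
  cat(sprintf("  cumulative explained variance: X %.1f%%, Y %.1f%%\n",
              sum(x$explained_x), sum(x$explained_y)))
  invisible(x)
}

#' Predict from a kernel PLS model
#'
#' Applies the stored column means and regression vector:
#' `yhat = (x - column_means) B + y_mean`; concentrations are the
#' back-transform `10^yhat`.
#'
#' @param object A `kernel_pls` fit.
#' @param new_data Numeric matrix with `p` matching columns, or a spectra
#'   tibble carrying the model's wavenumber columns.
#' @param ... Unused.
#' @return Tibble with columns `.pred_log10` and `.pred` (mg/kg DW), plus
#'   `sample` when available.
#' @export
predict.kernel_pls <- function(object, new_data, ...) {
  if (is.data.frame(new_data)) {
    samples <- if ("sample" %in% names(new_data)) new_data$sample else NULL
    if (!is.null(object$wavenumbers)) {
      wn <- as.character(object$wavenumbers)
      miss <- setdiff(wn, names(new_data))
      if (length(miss) > 0) {
        abort(paste0("new data lacks ", length(miss),
                     " model wavenumber column(s)"))
      }
      Xn <- as.matrix(new_data[, wn, drop = FALSE])
    } else {
      Xn <- spectra_matrix(new_data)
    }
  } else {
    samples <- rownames(new_data)
    Xn <- as.matrix(new_data)
  }
  if (ncol(Xn) != object$p) {
    abort(sprintf("expected %d columns, got %d", object$p, ncol(Xn)))
  }
  lp <- drop(sweep(Xn, 2, object$column_means) %*% object$coefficients) +
    object$y_mean
  out <- tibble::tibble(.pred_log10 = unname(lp), .pred = 10^unname(lp))
  if (!is.null(samples)) out <- dplyr::bind_cols(
    tibble::tibble(sample = samples), out)
  out
}

#' @rdname fit_kernel_pls
#' @param x,object A `kernel_pls` fit.
#' @param ... Unused.
#' @method tidy kernel_pls
#' @export
tidy.kernel_pls <- function(x, ...) {
  tibble::tibble(
    term = if (!is.null(x$wavenumbers)) as.character(x$wavenumbers)
           else paste0("x", seq_len(x$p)),
    wavenumber = if (!is.null(x$wavenumbers)) x$wavenumbers
                 else NA_real_,
    estimate = unname(x$coefficients)
  )
}

#' @rdname fit_kernel_pls
#' @method glance kernel_pls
#' @export
glance.kernel_pls <- function(x, ...) {
  tibble::tibble(
    ncomp = x$ncomp,
    rmsec = rmse_of(x$y, x$fitted),
    r2_cal = r2_pred_of(x$y, x$fitted),
    explained_x = sum(x$explained_x),
    explained_y = sum(x$explained_y),
    nobs = x$n,
    nvar = x$p
  )
}

#' Per-component explained variance
#'
#' @param model A `kernel_pls` fit.
#' @return Tibble with `ncomp`, `explained_x`, `explained_y` (percent per
#'   component) and their cumulative sums.
#' @export
explained_variance <- function(model) {
  tibble::tibble(
    ncomp = seq_len(model$ncomp),
    explained_x = model$explained_x,
    explained_y = model$explained_y,
    cum_explained_x = cumsum(model$explained_x),
    cum_explained_y = cumsum(model$explained_y)
  )
}

#' Calibration error metrics
#'
#' `rmse_of()` is the root mean square deviation `sqrt(sum((y - yhat)^2) /
#' N)` used for RMSEC (calibration fit), RMSECV (cross-validation) and
#' RMSEP (test-set prediction) alike. `bias_of()` is the mean signed error
#' `mean(yhat - y)`. `r2_pred_of()` is the squared Pearson correlation
#' between measured and predicted values; `method = "press"` gives the
#' `1 - PRESS/SS` alternative instead.
#'
#' @param y Measured values.
#' @param yhat Predicted values.
#' @param method For `r2_pred_of()`: `"cor"` (default) or `"press"`.
#' @return A single number.
#' @export
rmse_of <- function(y, yhat) {
  if (length(y) == 0) abort("empty input")
  if (length(y) != length(yhat)) abort("length mismatch")
  sqrt(mean((y - yhat)^2))
}

#' @rdname rmse_of
#' @export
bias_of <- function(y, yhat) {
  if (length(y) == 0) abort("empty input")
  mean(yhat - y)
}

#' @rdname rmse_of
#' @export
r2_pred_of <- function(y, yhat, method = c("cor", "press")) {
  method <- match.arg(method)
  if (method == "press") {
    return(1 - sum((y - yhat)^2) / sum((y - mean(y))^2))
  }
  pearson_r(y, yhat)^2
}

#' Venetian-blinds cross-validation of a PLS model
#'
#' For each fold, the model is refit on the remaining samples (re-centering
#' with training-fold means only) and the held-out samples are predicted;
#' RMSECV per component count is the root mean square of all held-out
#' errors. The retained component count is the smallest one whose RMSECV
#' lies within `tolerance` (default 2%) of the global minimum — the
#' parsimony rule.
#'
#' @param X Sample-by-variable matrix (raw scale).
#' @param y Response vector.
#' @param a_max Largest component count to try.
#' @param folds Integer fold assignment (see [venetian_blinds()]).
#' @param tolerance Relative slack for the parsimony rule.
#' @return List with `rmsecv` (tibble: `ncomp`, `rmsecv`) and `ncomp`
#'   (chosen component count).
#' @export
cross_validate_pls <- function(X, y, a_max, folds, tolerance = 0.02) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(folds) != n) abort("folds must assign every sample")
  sizes <- tabulate(folds)
  if (any(sizes == 0)) abort("empty cross-validation fold")
  if (any(n - sizes < a_max + 1)) {
    abort("a training fold has fewer than a_max + 1 samples")
  }
  pred <- matrix(NA_real_, n, a_max)
  for (m in sort(unique(folds))) {
    hold <- which(folds == m)
    train <- setdiff(seq_len(n), hold)
    fit <- fit_kernel_pls(X[train, , drop = FALSE], y[train], ncomp = a_max)
    Xh <- sweep(X[hold, , drop = FALSE], 2, fit$column_means)
    for (a in seq_len(fit$ncomp)) {
      Wa <- fit$weights[, seq_len(a), drop = FALSE]
      Pa <- fit$loadings[, seq_len(a), drop = FALSE]
      qa <- fit$y_loadings[seq_len(a)]
      Ba <- drop(Wa %*% solve(crossprod(Pa, Wa), qa))
      pred[hold, a] <- drop(Xh %*% Ba) + fit$y_mean
    }
    if (fit$ncomp < a_max) {
      pred[hold, (fit$ncomp + 1):a_max] <- pred[hold, fit$ncomp]
    }
  }
  rmsecv <- vapply(seq_len(a_max), function(a) rmse_of(y, pred[, a]),
                   numeric(1))
  best <- min(rmsecv)
  chosen <- which(rmsecv <= best * (1 + tolerance))[1]
  list(rmsecv = tibble::tibble(ncomp = seq_len(a_max), rmsecv = rmsecv),
       ncomp = as.integer(chosen))
}

#' Evaluate a PLS model on a test set
#'
#' @param model A `kernel_pls` fit.
#' @param X_test Test spectra matrix (raw scale, model variables).
#' @param y_test Test responses (log10 mg/kg DW).
#' @return One-row tibble: `rmsep`, `bias`, `r2_pred`, `n_test`.
#' @export
evaluate_pls <- function(model, X_test, y_test) {
  pred <- predict(model, X_test)
  tibble::tibble(
    rmsep = rmse_of(y_test, pred$.pred_log10),
    bias = bias_of(y_test, pred$.pred_log10),
    r2_pred = r2_pred_of(y_test, pred$.pred_log10),
    n_test = length(y_test)
  )
}

#' @rdname fit_kernel_pls
#' @method autoplot kernel_pls
#' @export
autoplot.kernel_pls <- function(object, ...) {
  df <- tibble::tibble(measured = object$y, predicted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Predicted log10 tomatine (mg/kg DW)",
                  y = "Measured log10 tomatine (mg/kg DW)",
                  title = "PLS calibration fit")
}
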