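#' Jackknife uncertainty test for PLS regression coefficients
#'
#' Significance test of each variable's regression coefficient across
#' cross-validation sub-models. The full model gives `B_tot`; each fold's
#' training complement gives a sub-model vector `B_m`. The jackknife
#' variance of coefficient `j` is
#' `s2_j = (M - 1) / M * sum_m (B_m[j] - B_tot[j])^2`
#' over the `M` folds, and variable `j` is significant at level `alpha`
#' when the interval `B_tot[j] +/- t_crit * sqrt(s2_j)` (Student t on
#' `M - 1` degrees of freedom) excludes zero. A coefficient with zero
#' jackknife variance is significant iff it is itself nonzero.
#'
#' @param X Sample-by-variable matrix (raw scale).
#' @param y Response vector (log10 mg/kg DW).
#' @param ncomp Latent variables for every (sub-)model.
#' @param folds Integer fold assignment (see [venetian_blinds()]), >= 2
#'   folds.
#' @param alpha Significance level (default 0.05, i.e. 95% confidence).
#' @return Tibble with one row per variable: `term`, `b_tot`, `se`
#'   (jackknife standard error), `statistic` (`|b_tot| / se`),
#'   `significant`. The number of folds is stored in the `n_folds`
#'   attribute.
#' @export
martens_uncertainty <- function(X, y, ncomp, folds, alpha = 0.05) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(folds) != n) abort("folds must assign every sample")
  fold_ids <- sort(unique(folds))
  M <- length(fold_ids)
  if (M < 2) abort("need at least 2 cross-validation folds")
  full <- fit_kernel_pls(X, y, ncomp = ncomp)
  b_tot <- full$coefficients
  B_sub <- vapply(fold_ids, function(m) {
    train <- which(folds != m)
    fit_kernel_pls(X[train, , drop = FALSE], y[train],
                   ncomp = min(ncomp, length(train) - 1L))$coefficients
  }, numeric(ncol(X)))
  if (!is.matrix(B_sub)) B_sub <- matrix(B_sub, nrow = ncol(X))
  s2 <- (M - 1) / M * rowSums((B_sub - b_tot)^2)
  se <- sqrt(s2)
  tcrit <- qt(1 - alpha / 2, df = M - 1)
  significant <- ifelse(se > 0,
                        abs(b_tot) > tcrit * se,
                        b_tot != 0)
  stat <- ifelse(se > 0, abs(b_tot) / se, ifelse(b_tot != 0, Inf, 0))
  out <- tibble::tibble(
    term = if (!is.null(full$wavenumbers)) as.character(full$wavenumbers)
           else paste0("x", seq_len(ncol(X))),
    b_tot = unname(b_tot),
    se = unname(se),
    statistic = unname(stat),
    significant = unname(significant)
  )
  attr(out, "n_folds") <- M
  out
}

#' Iterative uncertainty-test variable selection
#'
#' Repeatedly applies [martens_uncertainty()], dropping all non-significant
#' variables at once and refitting, and tracks the calibration /
#' cross-validation error gap `|RMSEC - RMSECV|`. Iteration stops when the
#' retained set stabilizes, when the gap increases relative to the previous
#' accepted iteration, or at `max_iter`; the returned mask is the one from
#' the iteration with the smallest gap. If a pass would eliminate every
#' variable, the previous mask is returned with a warning.
#'
#' @inheritParams martens_uncertainty
#' @param max_iter Iteration cap.
#' @return List of class `martens_selection`: `mask` (logical per original
#'   variable), `trace` (tibble: `iteration`, `p_retained`, `rmsec`,
#'   `rmsecv`, `gap`), `ncomp`, and `model` (the final refit on the
#'   selected variables).
#' @export
martens_selection <- function(X, y, ncomp, folds, alpha = 0.05,
                              max_iter = 20) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) abort("need at least 2 variables")
  min_train <- nrow(X) - max(tabulate(folds))
  evaluate_mask <- function(mask) {
    Xm <- X[, mask, drop = FALSE]
    a <- min(ncomp, ncol(Xm), min_train - 1L)
    fit <- fit_kernel_pls(Xm, y, ncomp = a)
    cv <- cross_validate_pls(Xm, y, a_max = a, folds = folds)
    rmsec <- rmse_of(y, fit$fitted)
    rmsecv <- cv$rmsecv$rmsecv[a]
    c(rmsec = rmsec, rmsecv = rmsecv, gap = abs(rmsec - rmsecv))
  }
  mask <- rep(TRUE, p)
  masks <- list(mask)
  ev <- evaluate_mask(mask)
  trace <- tibble::tibble(iteration = 1L, p_retained = p,
                          rmsec = unname(ev["rmsec"]), rmsecv = unname(ev["rmsecv"]),
                          gap = unname(ev["gap"]))
  iter <- 1L
  while (iter < max_iter) {
    a_cur <- min(ncomp, sum(mask))
    mu <- martens_uncertainty(X[, mask, drop = FALSE], y, ncomp = a_cur,
                              folds = folds, alpha = alpha)
    keep <- mu$significant
    if (!any(keep)) {
      warn("uncertainty test eliminated all variables; keeping previous set")
      break
    }
    new_mask <- mask
    new_mask[which(mask)[!keep]] <- FALSE
    if (identical(new_mask, mask)) break
    mask <- new_mask
    iter <- iter + 1L
    ev <- evaluate_mask(mask)
    masks[[iter]] <- mask
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      iteration = iter, p_retained = sum(mask),
      rmsec = unname(ev["rmsec"]), rmsecv = unname(ev["rmsecv"]), gap = unname(ev["gap"])))
    if (ev["gap"] > trace$gap[iter - 1L]) break
  }
  best <- which.min(trace$gap)
  mask <- masks[[best]]
  model <- fit_kernel_pls(X[, mask, drop = FALSE], y,
                          ncomp = min(ncomp, sum(mask)))
  structure(
    list(mask = mask, trace = trace, ncomp = model$ncomp, model = model,
         selected = if (!is.null(model$wavenumbers)) model$wavenumbers
                    else which(mask)),
    class = "martens_selection"
  )
}

#' @export
print.martens_selection <- function(x, ...) {
  cat(sprintf("Uncertainty-test variable selection: %d of %d variables retained in %d iteration(s)\n",
              sum(x$mask), length(x$mask), nrow(x$trace)))
  cat(sprintf("  final |RMSEC - RMSECV| gap: %.4g (initial %.4g)\n",
              x$trace$gap[which.min(x$trace$gap)], x$trace$gap[1]))
  invisible(x)
}

#' @rdname martens_selection
#' @param x A `martens_selection` object.
#' @param ... Unused.
#' @method tidy martens_selection
#' @export
tidy.martens_selection <- function(x, ...) x$trace

#' @rdname martens_selection
#' @param object A `martens_selection` object.
#' @method autoplot martens_selection
#' @export
autoplot.martens_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, c("rmsec", "rmsecv"),
                            names_to = "metric", values_to = "error")
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$error,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Selection iteration", y = "Error (log10 mg/kg DW)",
                  colour = NULL, title = "Uncertainty-test iteration trace")
}
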