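#' Pearson correlation with validity checks
#'
#' Plain Pearson product-moment correlation, erroring on the degenerate
#' inputs (length < 3, constant vectors) that silently yield `NA` in
#' [stats::cor()].
#'
#' @param a,b Numeric vectors of equal length (>= 3).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort("vectors must have equal length")
  if (length(a) < 3) abort("need at least 3 observations")
  if (sd(a) == 0 || sd(b) == 0) {
    abort("correlation undefined for a constant vector")
  }
  cor(a, b)
}

#' Zero-intercept calibration of log10 tomatine on thermogravimetric features
#'
#' Fits the through-origin multiple linear regression
#' \deqn{y = b_1 x_1 + b_2 x_2}
#' where \eqn{y} is log10 tomatine (mg/kg DW) and \eqn{x_1, x_2} are the
#' weight-loss percentages in the 120-200 and 200-400 degree ranges. The
#' intercept is omitted because it is not significantly different from zero
#' on the reference data; `with_intercept = TRUE` exposes that test by
#' fitting the intercept model instead (its p-value is reported so the
#' forced-zero choice can be re-justified on new data).
#'
#' Conventions for a through-origin fit: R-squared is the uncentered form
#' `1 - SSE / sum(y^2)`; adjusted R-squared is `1 - (1 - R2) * n / (n - 2)`;
#' model RMSE is the residual standard error `sqrt(SSE / (n - 2))`;
#' coefficient t-tests and the overall F-test use `n - 2` residual degrees
#' of freedom.
#'
#' @param data Tibble with columns `x1`, `x2`, `y` (see
#'   [assemble_calibration_set()]).
#' @param with_intercept Fit an intercept term instead of forcing it to zero.
#' @return Object of class `tga_mlr`: the underlying [stats::lm] fit plus
#'   calibration metadata. Supports [tidy()], [glance()], [augment()],
#'   [predict()][predict.tga_mlr] and [autoplot()].
#' @examples
#' cal <- assemble_calibration_set(load_table1(), load_table2())
#' fit <- fit_tga_mlr(cal)
#' glance(fit)
#' @export
fit_tga_mlr <- function(data, with_intercept = FALSE) {
  need <- c("x1", "x2", "y")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort(paste0("data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  n <- nrow(data)
  if (n < 3) abort("need at least 3 samples to fit")
  X <- cbind(data$x1, data$x2)
  if (qr(X)$rank < 2) abort("x1 and x2 are collinear: rank-deficient design")
  fml <- if (with_intercept) y ~ x1 + x2 else y ~ 0 + x1 + x2
  fit <- lm(fml, data = data)
  structure(
    list(
      lm = fit,
      data = tibble::as_tibble(data),
      with_intercept = with_intercept,
      n = n
    ),
    class = "tga_mlr"
  )
}

#' @export
print.tga_mlr <- function(x, ...) {
  b <- coef(x$lm)
  cat("Zero-intercept TGA calibration (log10 tomatine)\n")
  if (x$with_intercept) cat("  (refit with intercept)\n")
  cat(sprintf("  coefficients: %s\n",
              paste(sprintf("%s = %.4f", names(b), b), collapse = ", ")))
  g <- glance(x)
  cat(sprintf("  n = %d, R2 = %.4f, adj R2 = %.4f, RMSE = %.4f\n",
              x$n, g$r.squared, g$adj.r.squared, g$rmse))
  invisible(x)
}

#' @rdname fit_tga_mlr
#' @param x A `tga_mlr` object.
#' @param ... Unused.
#' @method tidy tga_mlr
#' @export
tidy.tga_mlr <- function(x, ...) {
  s <- summary(x$lm)$coefficients
  tibble::tibble(
    term = rownames(s),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @rdname fit_tga_mlr
#' @method glance tga_mlr
#' @export
glance.tga_mlr <- function(x, ...) {
  res <- resid(x$lm)
  n <- x$n
  p <- length(coef(x$lm))
  sse <- sum(res^2)
  s <- summary(x$lm)
  fstat <- s$fstatistic
  tibble::tibble(
    r.squared = s$r.squared,
    adj.r.squared = s$adj.r.squared,
    rmse = sqrt(sse / (n - p)),
    statistic = unname(fstat[1]),
    p.value = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    df.residual = n - p,
    nobs = n
  )
}

#' @rdname fit_tga_mlr
#' @method augment tga_mlr
#' @export
augment.tga_mlr <- function(x, ...) {
  dplyr::mutate(
    x$data,
    .fitted = unname(predict(x$lm)),
    .resid = unname(resid(x$lm)),
    .std.resid = autoscaled_residuals(x)
  )
}

#' Predict tomatine concentration from thermogravimetric features
#'
#' Back-transforms the linear predictor to the concentration scale:
#' `10^(b1 * x1 + b2 * x2)` mg/kg DW. Reported integer values round half
#' away from zero, matching how the reference comparisons are printed.
#'
#' @param object A `tga_mlr` fit.
#' @param new_data Tibble with columns `x1`, `x2` (defaults to the
#'   calibration data).
#' @param ... Unused.
#' @return `new_data` with `.pred_log10` (log10 mg/kg), `.pred` (mg/kg) and
#'   `.pred_mgkg` (integer-rounded mg/kg) columns appended.
#' @export
predict.tga_mlr <- function(object, new_data = NULL, ...) {
  if (is.null(new_data)) new_data <- object$data
  miss <- setdiff(c("x1", "x2"), names(new_data))
  if (length(miss) > 0) {
    abort(paste0("new_data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  lp <- unname(predict(object$lm, newdata = new_data))
  dplyr::mutate(
    tibble::as_tibble(new_data),
    .pred_log10 = lp,
    .pred = 10^lp,
    .pred_mgkg = round_half_away(10^lp)
  )
}

# round-half-away-from-zero to integer (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Autoscaled (standardized) residuals of a calibration fit
#'
#' Raw residuals divided by their own sample standard deviation. The mean
#' of through-origin residuals is not forced to zero, so the residuals are
#' scaled, not centered-and-scaled; values should fall within roughly
#' plus/minus 3 (a 99% band) for a well-behaved calibration.
#'
#' @param model A `tga_mlr` fit.
#' @return Dimensionless numeric vector, one value per calibration sample.
#' @export
autoscaled_residuals <- function(model) {
  res <- unname(resid(model$lm))
  s <- sd(res)
  if (s == 0) return(res * 0)
  res / s
}

#' Per-stage summary of thermogravimetric weight losses
#'
#' Mean and sample standard deviation of a weight-loss feature across
#' varieties, by ripening stage.
#'
#' @param tga Tibble in the [load_table2()] schema.
#' @param range `"120_200"` or `"200_400"` (temperature range, degrees C).
#' @return Tibble with columns `stage`, `n`, `mean`, `sd`, ordered
#'   green/turning/pink/red. Stages with fewer than 2 samples are dropped
#'   with a warning.
#' @examples
#' stage_summary(load_table2(), "200_400")
#' @export
stage_summary <- function(tga, range = c("120_200", "200_400")) {
  range <- match.arg(range)
  col <- paste0("wl_", range)
  out <- tga |>
    dplyr::group_by(stage = factor(.data$stage, levels = stage_levels)) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data[[col]]),
      sd = sd(.data[[col]]),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$stage) |>
    dplyr::mutate(stage = as.character(.data$stage))
  thin <- out$n < 2
  if (any(thin)) {
    warn(paste0("dropping stage(s) with < 2 samples: ",
                paste(out$stage[thin], collapse = ", ")))
    out <- out[!thin, , drop = FALSE]
  }
  out
}

#' @rdname fit_tga_mlr
#' @param object A `tga_mlr` fit.
#' @method autoplot tga_mlr
#' @export
autoplot.tga_mlr <- function(object, ...) {
  aug <- augment(object)
  meas_pred <- ggplot2::ggplot(aug, ggplot2::aes(.data$.fitted, .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Predicted log10 tomatine (mg/kg DW)",
                  y = "Measured log10 tomatine (mg/kg DW)",
                  title = "TGA/MLR calibration")
  resid_plot <- ggplot2::ggplot(aug,
                                ggplot2::aes(.data$.fitted,
                                             .data$.std.resid)) +
    ggplot2::geom_hline(yintercept = c(-3, 0, 3), linetype = c(2, 1, 2),
                        colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Predicted log10 tomatine (mg/kg DW)",
                  y = "Autoscaled residual",
                  title = "Residual diagnostics")
  list(measured_vs_predicted = meas_pred, residuals = resid_plot)
}
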