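# Independent oracles used across test files.

# closed-form normal equations for the two-feature through-origin fit
normal_eq_coefs <- function(x1, x2, y) {
  XtX <- matrix(c(sum(x1^2), sum(x1 * x2), sum(x1 * x2), sum(x2^2)), 2, 2)
  drop(solve(XtX, c(sum(x1 * y), sum(x2 * y))))
}

# Savitzky-Golay by explicit local polynomial least squares: for each full
# window, fit a polynomial in the centered index and read off the deriv-th
# derivative at the center point.
sg_polyfit_oracle <- function(row, window, polyorder, deriv) {
  half <- (window - 1) / 2
  idx <- (half + 1):(length(row) - half)
  j <- -half:half
  vapply(idx, function(i) {
    fit <- lm(row[(i - half):(i + half)] ~ poly(j, polyorder, raw = TRUE))
    factorial(deriv) * coef(fit)[[deriv + 1]]
  }, numeric(1))
}

# loop-written cross-validation oracle: refits from scratch per fold and per
# component count (no nested-component shortcut)
cv_oracle <- function(X, y, a_max, folds) {
  vapply(seq_len(a_max), function(a) {
    pred <- numeric(length(y))
    for (m in sort(unique(folds))) {
      hold <- which(folds == m)
      train <- which(folds != m)
      fit <- fit_kernel_pls(X[train, , drop = FALSE], y[train], ncomp = a)
      pred[hold] <- predict(fit, X[hold, , drop = FALSE])$.pred_log10
    }
    sqrt(mean((y - pred)^2))
  }, numeric(1))
}

# end-to-end synthetic benchmark over a fixed block of seeds
run_spectra_benchmark <- function(seeds) {
  purrr::map_dfr(seq_along(seeds), function(i) {
    ds <- generate_spectra_dataset(seed = 1000 + seeds[i])
    route <- suppressWarnings(
      run_pls_route(ds$spectra, ds$response, seed = seeds[i]))
    bands <- ds$truth$analyte_bands
    covered <- purrr::pmap_lgl(
      bands[, c("center", "width")],
      function(center, width) {
        any(abs(route$selected_wavenumbers - center) <= width)
      })
    tibble::tibble(
      seed = seeds[i],
      r2_pred = route$evaluation$r2_pred,
      bias = route$evaluation$bias,
      rmsep = route$evaluation$rmsep,
      all_bands_retained = all(covered),
      band_coverage = mean(covered),
      gap_returned = min(route$selection$trace$gap),
      gap_initial = route$selection$trace$gap[1]
    )
  })
}

expected_table4_tga <- function() {
  load_table4()$predicted_tga_mlr
}
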