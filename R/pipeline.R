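#' Run the thermogravimetric calibration route end to end
#'
#' Assembles the calibration table from the reference fixtures (or
#' user-supplied tables in the same schema), fits the zero-intercept MLR on
#' log10 tomatine, and produces the inference statistics, standardized
#' residuals, feature correlations and the back-transformed per-sample
#' predictions alongside the reference concentrations.
#'
#' @param glyco Glycoalkaloid table ([load_table1()] schema).
#' @param tga Thermogravimetric table ([load_table2()] schema).
#' @param exclude Sample keys dropped before fitting (default the red-stage
#'   leverage outlier; it has no thermogravimetric row in the reference
#'   fixtures, so excluding it there is a no-op logged for transparency).
#' @param out_dir Optional directory; when given, writes `tga_model.json`,
#'   `tga_statistics.csv` and `tga_predictions.csv`.
#' @return List of class `tga_route`: `model`, `coefficients` (tidy),
#'   `statistics` (glance), `correlations`, `samples` (augmented
#'   calibration data) and `predictions` (variety, stage, reference and
#'   predicted mg/kg DW).
#' @examples
#' route <- run_tga_route()
#' route$predictions
#' @export
run_tga_route <- function(glyco = load_table1(), tga = load_table2(),
                          exclude = "H7204_red", out_dir = NULL) {
  cal <- assemble_calibration_set(glyco, tga, exclude = exclude)
  model <- fit_tga_mlr(cal)
  correlations <- tibble::tibble(
    feature = c("wl_120_200", "wl_200_400"),
    pearson_r = c(pearson_r(cal$y, cal$x1), pearson_r(cal$y, cal$x2))
  )
  preds <- predict(model) |>
    dplyr::transmute(
      variety = .data$variety, stage = .data$stage,
      reference = .data$tomatine,
      predicted = .data$.pred_mgkg,
      predicted_log10 = .data$.pred_log10
    )
  out <- structure(
    list(model = model,
         coefficients = tidy(model),
         statistics = glance(model),
         correlations = correlations,
         samples = augment(model),
         predictions = preds),
    class = "tga_route"
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(
      list(coefficients = as.list(setNames(out$coefficients$estimate,
                                           out$coefficients$term)),
           statistics = as.list(out$statistics),
           exclude = exclude,
           provenance = route_provenance(list(exclude = exclude))),
      file.path(out_dir, "tga_model.json"), auto_unbox = TRUE, digits = NA)
    readr::write_csv(out$statistics, file.path(out_dir, "tga_statistics.csv"),
                     progress = FALSE)
    readr::write_csv(preds, file.path(out_dir, "tga_predictions.csv"),
                     progress = FALSE)
  }
  out
}

#' @export
print.tga_route <- function(x, ...) {
  print(x$model)
  cat(sprintf("  Pearson r: wl_120_200 %.3f, wl_200_400 %.3f\n",
              x$correlations$pearson_r[1], x$correlations$pearson_r[2]))
  invisible(x)
}

#' Run the spectral calibration route end to end
#'
#' Full chemometric chain on replicate spectra: replicate averaging, region
#' selection, standard normal variate, Savitzky-Golay second derivative,
#' random calibration/test split, venetian-blinds cross-validation to pick
#' the component count, iterative uncertainty-test variable selection, a
#' final refit on the retained wavenumbers and external validation on the
#' held-out test set.
#'
#' @param spectra Replicate-level spectra tibble (see [read_spectra_csv()]).
#' @param response Tibble with columns `sample`, `y` (log10 tomatine).
#' @param region Modeling window, cm^-1.
#' @param apply_snv Apply SNV before the derivative.
#' @param sg_window,sg_polyorder,sg_deriv Savitzky-Golay settings.
#' @param calibration_fraction Calibration share of the random split.
#' @param cv_segments Venetian-blinds fold count.
#' @param a_max Largest component count scanned by cross-validation.
#' @param ncomp Force the component count (e.g. 3) instead of the
#'   RMSECV parsimony rule.
#' @param alpha Uncertainty-test significance level.
#' @param max_iter Selection iteration cap.
#' @param seed Integer seed driving the random split.
#' @param out_dir Optional directory; writes `pls_evaluation.csv`,
#'   `pls_trace.csv`, `pls_selected_wavenumbers.csv`,
#'   `pls_predictions.csv` and `pls_report.json`.
#' @return List of class `pls_route`: `model` (final `kernel_pls`),
#'   `selection` (`martens_selection`), `rmsecv` (tibble per component),
#'   `evaluation` (one-row tibble: `ncomp`, `n_selected`, `rmsec`,
#'   `rmsecv`, `rmsep`, `bias`, `r2_cal`, `r2_pred`), `predictions`
#'   (test-set measured vs predicted), `split`, and `selected_wavenumbers`.
#' @examples
#' ds <- generate_spectra_dataset(seed = 7)
#' route <- run_pls_route(ds$spectra, ds$response, seed = 7)
#' route$evaluation
#' @export
run_pls_route <- function(spectra, response,
                          region = c(752, 1800),
                          apply_snv = TRUE,
                          sg_window = 7, sg_polyorder = 2, sg_deriv = 2,
                          calibration_fraction = 0.75,
                          cv_segments = 4,
                          a_max = 6, ncomp = NULL,
                          alpha = 0.05, max_iter = 20,
                          seed, out_dir = NULL) {
  prep <- spectra |>
    average_replicates() |>
    attach_response(response) |>
    select_region(region[1], region[2])
  if (apply_snv) prep <- snv(prep)
  prep <- sg_derivative(prep, window = sg_window, polyorder = sg_polyorder,
                        deriv = sg_deriv)
  X <- spectra_matrix(prep)
  y <- prep$y
  n <- nrow(X)
  split <- split_calibration_test(n, calibration_fraction, seed = seed)
  Xcal <- X[split$calibration, , drop = FALSE]
  ycal <- y[split$calibration]
  folds <- venetian_blinds(nrow(Xcal), cv_segments)
  a_max_eff <- min(a_max, nrow(Xcal) - max(tabulate(folds)) - 1L)
  cv <- cross_validate_pls(Xcal, ycal, a_max = a_max_eff, folds = folds)
  A <- if (is.null(ncomp)) cv$ncomp else min(ncomp, a_max_eff)
  sel <- martens_selection(Xcal, ycal, ncomp = A, folds = folds,
                           alpha = alpha, max_iter = max_iter)
  model <- sel$model
  Xtest <- X[split$test, sel$mask, drop = FALSE]
  ytest <- y[split$test]
  ev_test <- evaluate_pls(model, Xtest, ytest)
  best <- which.min(sel$trace$gap)
  evaluation <- tibble::tibble(
    ncomp = model$ncomp,
    n_selected = sum(sel$mask),
    rmsec = rmse_of(ycal, model$fitted),
    rmsecv = sel$trace$rmsecv[best],
    rmsep = ev_test$rmsep,
    bias = ev_test$bias,
    r2_cal = r2_pred_of(ycal, model$fitted),
    r2_pred = ev_test$r2_pred
  )
  predictions <- dplyr::bind_cols(
    tibble::tibble(sample = prep$sample[split$test], measured = ytest),
    predict(model, Xtest)[, c(".pred_log10", ".pred")]
  )
  config <- list(region = region, apply_snv = apply_snv,
                 sg_window = sg_window, sg_polyorder = sg_polyorder,
                 sg_deriv = sg_deriv,
                 calibration_fraction = calibration_fraction,
                 cv_segments = cv_segments, a_max = a_max, ncomp = ncomp,
                 alpha = alpha, max_iter = max_iter, seed = seed)
  out <- structure(
    list(model = model, selection = sel, rmsecv = cv$rmsecv,
         evaluation = evaluation, predictions = predictions,
         split = split, selected_wavenumbers = sel$selected,
         config = config),
    class = "pls_route"
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(evaluation, file.path(out_dir, "pls_evaluation.csv"),
                     progress = FALSE)
    readr::write_csv(sel$trace, file.path(out_dir, "pls_trace.csv"),
                     progress = FALSE)
    readr::write_csv(tibble::tibble(wavenumber = sel$selected),
                     file.path(out_dir, "pls_selected_wavenumbers.csv"),
                     progress = FALSE)
    readr::write_csv(predictions, file.path(out_dir, "pls_predictions.csv"),
                     progress = FALSE)
    jsonlite::write_json(
      list(evaluation = as.list(evaluation),
           provenance = route_provenance(config)),
      file.path(out_dir, "pls_report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.pls_route <- function(x, ...) {
  e <- x$evaluation
  cat("Spectral calibration route (SNV -> SG2 -> kernel PLS -> uncertainty test)\n")
  cat(sprintf("  %d latent variable(s), %d retained wavenumber(s)\n",
              e$ncomp, e$n_selected))
  cat(sprintf("  RMSEC %.3f, RMSECV %.3f, RMSEP %.3f (log10 mg/kg DW)\n",
              e$rmsec, e$rmsecv, e$rmsep))
  cat(sprintf("  R2 cal %.3f, R2 pred %.3f, BIAS %.3f\n",
              e$r2_cal, e$r2_pred, e$bias))
  invisible(x)
}

route_provenance <- function(config) {
  list(package = "tomachem",
       version = as.character(utils::packageVersion("tomachem")),
       config_hash = rlang::hash(config))
}

#' Combined report over both calibration routes
#'
#' Merges the per-sample prediction tables of the thermogravimetric and
#' spectral routes with the reference concentrations, and stacks their
#' headline metrics, mirroring the reference-versus-predicted comparison
#' layout.
#'
#' @param tga_route Result of [run_tga_route()] (or `NULL`).
#' @param pls_route Result of [run_pls_route()] (or `NULL`).
#' @param out_dir Optional directory; writes `report_samples.csv` and
#'   `report_metrics.csv`.
#' @return List of class `pipeline_report`: `samples` (merged per-sample
#'   table), `metrics`, `provenance`.
#' @export
pipeline_report <- function(tga_route = NULL, pls_route = NULL,
                            out_dir = NULL) {
  if (is.null(tga_route) && is.null(pls_route)) {
    abort("at least one route report is required")
  }
  samples <- NULL
  metrics <- NULL
  if (!is.null(tga_route)) {
    samples <- dplyr::select(tga_route$predictions, "variety", "stage",
                             "reference", predicted_tga_mlr = "predicted")
    g <- tga_route$statistics
    metrics <- tibble::tibble(
      route = "tga_mlr",
      metric = c("r_squared", "adj_r_squared", "rmse"),
      value = c(g$r.squared, g$adj.r.squared, g$rmse)
    )
  }
  if (!is.null(pls_route)) {
    e <- pls_route$evaluation
    pls_metrics <- tibble::tibble(
      route = "ftir_pls",
      metric = c("rmsec", "rmsecv", "rmsep", "r2_cal", "r2_pred", "bias",
                 "ncomp", "n_selected"),
      value = c(e$rmsec, e$rmsecv, e$rmsep, e$r2_cal, e$r2_pred, e$bias,
                e$ncomp, e$n_selected)
    )
    metrics <- dplyr::bind_rows(metrics, pls_metrics)
    pls_samples <- dplyr::transmute(
      pls_route$predictions,
      sample = .data$sample,
      measured_log10 = .data$measured,
      predicted_ftir_pls = .data$.pred
    )
    samples <- if (is.null(samples)) pls_samples else samples
  }
  provenance <- route_provenance(list(
    tga = !is.null(tga_route),
    pls = if (!is.null(pls_route)) pls_route$config else NULL
  ))
  out <- structure(
    list(samples = samples, metrics = metrics, provenance = provenance),
    class = "pipeline_report"
  )
  if (!is.null(pls_route) && !is.null(tga_route)) {
    out$pls_test_samples <- dplyr::transmute(
      pls_route$predictions, sample = .data$sample,
      measured_log10 = .data$measured, predicted_ftir_pls = .data$.pred)
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(samples, file.path(out_dir, "report_samples.csv"),
                     progress = FALSE)
    readr::write_csv(metrics, file.path(out_dir, "report_metrics.csv"),
                     progress = FALSE)
  }
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Calibration pipeline report (config ",
      x$provenance$config_hash, ")\n", sep = "")
  print(x$metrics, n = nrow(x$metrics))
  invisible(x)
}
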