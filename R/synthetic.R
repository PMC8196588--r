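#' Synthetic thermogravimetric calibration data
#'
#' Draws samples with the statistical structure the TGA calibration
#' assumes: weight-loss features `x1`, `x2` uniform over the ranges the
#' reference samples span, and a log10 tomatine response generated by the
#' through-origin linear model `y = beta1 x1 + beta2 x2 + e`,
#' `e ~ N(0, noise_sd)`. Defaults reproduce the reference study
#' conditions: 22 samples, coefficients (-0.0472, 0.0983), feature ranges
#' 14-25% and 33-41%, residual scale 0.11 log10 units.
#'
#' @param n Number of samples.
#' @param beta1,beta2 Generating coefficients (per percent weight loss).
#' @param x1_range,x2_range Feature ranges (percent).
#' @param noise_sd Residual standard deviation, log10 units.
#' @param seed Integer seed; the dataset is a pure function of the
#'   arguments.
#' @return List with `data` (tibble: `sample`, `x1`, `x2`, `y`, `tomatine`)
#'   and `truth` (the generating parameters).
#' @examples
#' ds <- generate_tga_dataset(seed = 1)
#' fit_tga_mlr(ds$data)
#' @export
generate_tga_dataset <- function(n = 22, beta1 = -0.0472, beta2 = 0.0983,
                                 x1_range = c(14, 25), x2_range = c(33, 41),
                                 noise_sd = 0.11, seed) {
  if (diff(x1_range) <= 0 || diff(x2_range) <= 0) {
    abort("feature ranges must be non-degenerate")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  data <- with_seed(seed, {
    x1 <- runif(n, x1_range[1], x1_range[2])
    x2 <- runif(n, x2_range[1], x2_range[2])
    y <- beta1 * x1 + beta2 * x2 + rnorm(n, sd = noise_sd)
    tibble::tibble(
      sample = sprintf("s%02d", seq_len(n)),
      x1 = x1, x2 = x2, y = y, tomatine = 10^y
    )
  })
  list(data = data,
       truth = list(beta1 = beta1, beta2 = beta2, noise_sd = noise_sd,
                    seed = seed))
}

#' Default band inventory for the spectral simulator
#'
#' Matrix (background) bands are seeded from the mid-infrared band
#' assignments of dried tomato (esters, amides, aromatics, carbohydrate
#' C-O-C modes); per-sample lognormal jitter of their amplitudes gives the
#' X-block variance unrelated to the analyte. Analyte bands sit in the
#' 950-1100 cm^-1 window where tomatine absorbs, with amplitudes
#' proportional to log10 concentration.
#'
#' @return Tibbles with columns `center` (cm^-1), `width` (Gaussian sd,
#'   cm^-1) and `amplitude` (absorbance units; for analyte bands, per log10
#'   unit of tomatine).
#' @export
default_matrix_bands <- function() {
  centers <- load_table3()$wavenumber
  tibble::tibble(
    center = centers,
    width = c(18, 22, 14, 14, 16, 18, 18, 16, 12, 14, 35, 12),
    amplitude = c(0.35, 0.55, 0.20, 0.18, 0.40, 0.30, 0.28, 0.25,
                  0.30, 0.45, 1.00, 0.30)
  )
}

#' @rdname default_matrix_bands
#' @export
default_analyte_bands <- function() {
  tibble::tibble(
    center = c(985, 1050, 1095),
    width = c(12, 15, 10),
    amplitude = c(0.25, 0.20, 0.15)
  )
}

#' Synthetic mid-infrared spectra with a tomatine signal
#'
#' Simulates replicate ATR-style absorbance spectra on a fingerprint-region
#' grid. Each sample's clean spectrum is a sum of Gaussian matrix bands
#' (amplitudes jittered per sample) plus Gaussian analyte bands scaled by
#' the sample's log10 tomatine; each replicate then receives multiplicative
#' scatter, an additive baseline offset and pointwise noise:
#' `rep = clean * (1 + m) + b + e`. Responses are uniform on the log10
#' scale over `y_range` (default spans roughly 141-1993 mg/kg DW).
#'
#' @param n_samples Number of samples (default 22).
#' @param replicates Replicates per sample (default 3).
#' @param grid Wavenumber axis, cm^-1 (default 752-1800 at 2 cm^-1).
#' @param matrix_bands,analyte_bands Band tibbles (`center`, `width`,
#'   `amplitude`); see [default_matrix_bands()].
#' @param y_range Log10 tomatine range (mg/kg DW).
#' @param matrix_jitter_sdlog Lognormal sd of per-sample matrix-band
#'   amplitude jitter.
#' @param multiplicative_scatter_sd Sd of the per-replicate gain deviation.
#' @param baseline_offset_sd Sd of the per-replicate additive offset.
#' @param replicate_noise_sd Sd of pointwise replicate noise.
#' @param seed Integer seed.
#' @return List with `spectra` (replicate-level spectra tibble), `clean`
#'   (noise-free per-sample spectra tibble), `response` (tibble: `sample`,
#'   `y`, `tomatine`) and `truth` (analyte bands, informative wavenumbers
#'   within one width of each analyte center, and the config).
#' @examples
#' ds <- generate_spectra_dataset(seed = 7)
#' dim(ds$spectra)
#' @export
generate_spectra_dataset <- function(n_samples = 22,
                                     replicates = 3,
                                     grid = seq(752, 1800, by = 2),
                                     matrix_bands = default_matrix_bands(),
                                     analyte_bands = default_analyte_bands(),
                                     y_range = c(2.15, 3.30),
                                     matrix_jitter_sdlog = 0.05,
                                     multiplicative_scatter_sd = 0.05,
                                     baseline_offset_sd = 0.02,
                                     replicate_noise_sd = 0.002,
                                     seed) {
  if (any(matrix_bands$width <= 0) || any(analyte_bands$width <= 0)) {
    abort("band widths must be > 0")
  }
  if (any(analyte_bands$center < min(grid) |
            analyte_bands$center > max(grid))) {
    abort("analyte band centers must lie inside the grid")
  }
  if (diff(y_range) <= 0) abort("y_range must be increasing")

  gauss <- function(center, width) exp(-((grid - center)^2) / (2 * width^2))
  analyte_profile <- Reduce(`+`, purrr::pmap(analyte_bands, function(center, width, amplitude) {
    amplitude * gauss(center, width)
  }))

  out <- with_seed(seed, {
    y <- runif(n_samples, y_range[1], y_range[2])
    sample_ids <- sprintf("s%02d", seq_len(n_samples))
    clean <- matrix(0, n_samples, length(grid))
    for (i in seq_len(n_samples)) {
      jit <- exp(rnorm(nrow(matrix_bands), sd = matrix_jitter_sdlog))
      for (b in seq_len(nrow(matrix_bands))) {
        clean[i, ] <- clean[i, ] + matrix_bands$amplitude[b] * jit[b] *
          gauss(matrix_bands$center[b], matrix_bands$width[b])
      }
      clean[i, ] <- clean[i, ] + y[i] * analyte_profile
    }
    reps <- vector("list", n_samples * replicates)
    rep_ids <- character(n_samples * replicates)
    k <- 0L
    for (i in seq_len(n_samples)) {
      for (r in seq_len(replicates)) {
        k <- k + 1L
        m <- rnorm(1, sd = multiplicative_scatter_sd)
        b0 <- rnorm(1, sd = baseline_offset_sd)
        eps <- rnorm(length(grid), sd = replicate_noise_sd)
        reps[[k]] <- clean[i, ] * (1 + m) + b0 + eps
        rep_ids[k] <- sprintf("%s_r%d", sample_ids[i], r)
      }
    }
    list(y = y, sample_ids = sample_ids, clean = clean,
         X = do.call(rbind, reps), rep_ids = rep_ids)
  })

  informative <- sort(unique(unlist(purrr::pmap(
    analyte_bands[, c("center", "width")],
    function(center, width) grid[abs(grid - center) <= width]))))

  spectra <- rebuild_spectra(out$X, grid, tibble::tibble(sample = out$rep_ids))
  clean_tbl <- rebuild_spectra(out$clean, grid,
                               tibble::tibble(sample = out$sample_ids))
  list(
    spectra = spectra,
    clean = clean_tbl,
    response = tibble::tibble(sample = out$sample_ids, y = out$y,
                              tomatine = 10^out$y),
    truth = list(
      analyte_bands = analyte_bands,
      informative_wavenumbers = informative,
      y = out$y,
      config = list(n_samples = n_samples, replicates = replicates,
                    y_range = y_range,
                    matrix_jitter_sdlog = matrix_jitter_sdlog,
                    multiplicative_scatter_sd = multiplicative_scatter_sd,
                    baseline_offset_sd = baseline_offset_sd,
                    replicate_noise_sd = replicate_noise_sd,
                    seed = seed)
    )
  )
}

#' Write a synthetic spectra dataset to disk
#'
#' Emits the replicate spectra as a wavenumber-first wide CSV, the
#' responses as a CSV and the generator truth as JSON, creating the
#' directory if needed. Files round-trip through [read_spectra_csv()] /
#' [read_sample_table()].
#'
#' @param ds Dataset from [generate_spectra_dataset()].
#' @param dir Output directory.
#' @return Named character vector of file paths, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    spectra = file.path(dir, "spectra.csv"),
    response = file.path(dir, "response.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_spectra_csv(ds$spectra, paths[["spectra"]])
  readr::write_csv(ds$response, paths[["response"]], progress = FALSE)
  jsonlite::write_json(
    list(analyte_bands = ds$truth$analyte_bands,
         informative_wavenumbers = ds$truth$informative_wavenumbers,
         config = ds$truth$config),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
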