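#' Spectra tables
#'
#' Spectra travel through the pipeline as a tibble with one row per
#' spectrum: a `sample` column (replicates named `<sample>_r<k>`), an
#' optional `y` response column (log10 tomatine, mg/kg DW), and one numeric
#' column per wavenumber, named by its value in cm^-1 (e.g. `"752"`,
#' `"754"`). The on-disk interchange format is the transposed wide CSV
#' common to spectroscopy software: column 1 `wavenumber` (strictly
#' monotonic, cm^-1), one column per spectrum.
#'
#' @param path CSV file in the wavenumber-first wide layout.
#' @param tbl A spectra tibble.
#' @return `read_spectra_csv()` returns a spectra tibble;
#'   `write_spectra_csv()` returns `path` invisibly;
#'   `spectra_wavenumbers()` the numeric wavenumber axis;
#'   `spectra_matrix()` the samples-by-wavenumbers numeric matrix.
#' @name spectra_table
NULL

#' @rdname spectra_table
#' @export
read_spectra_csv <- function(path) {
  wide <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (names(wide)[1] != "wavenumber") {
    abort(paste0(path, ": first column must be 'wavenumber'"))
  }
  wn <- wide$wavenumber
  if (any(diff(wn) <= 0)) {
    abort(paste0(path, ": wavenumber axis must be strictly increasing"))
  }
  X <- t(as.matrix(wide[, -1, drop = FALSE]))
  out <- tibble::as_tibble(X, .name_repair = "minimal")
  names(out) <- as.character(wn)
  dplyr::bind_cols(tibble::tibble(sample = names(wide)[-1]), out)
}

#' @rdname spectra_table
#' @export
write_spectra_csv <- function(tbl, path) {
  wn <- spectra_wavenumbers(tbl)
  X <- spectra_matrix(tbl)
  wide <- tibble::as_tibble(t(X), .name_repair = "minimal")
  names(wide) <- tbl$sample
  wide <- dplyr::bind_cols(tibble::tibble(wavenumber = wn), wide)
  readr::write_csv(wide, path, progress = FALSE)
  invisible(path)
}

#' @rdname spectra_table
#' @export
spectra_wavenumbers <- function(tbl) {
  wn <- suppressWarnings(as.numeric(names(tbl)))
  wn[!is.na(wn)]
}

#' @rdname spectra_table
#' @export
spectra_matrix <- function(tbl) {
  keep <- !is.na(suppressWarnings(as.numeric(names(tbl))))
  X <- as.matrix(tbl[, keep, drop = FALSE])
  rownames(X) <- tbl$sample
  X
}

# rebuild a spectra tibble from a matrix, keeping non-spectral columns of ref
rebuild_spectra <- function(X, wavenumbers, ref) {
  keep <- is.na(suppressWarnings(as.numeric(names(ref))))
  meta <- ref[, keep, drop = FALSE]
  out <- tibble::as_tibble(X, .name_repair = "minimal")
  names(out) <- as.character(wavenumbers)
  dplyr::bind_cols(meta, out)
}

#' Average replicate spectra
#'
#' Collapses replicate rows (sample names `<sample>_r<k>`) to one spectrum
#' per sample by the pointwise mean. Rows lacking a replicate suffix are
#' treated as single-replicate samples. Output rows are sorted by sample
#' name, with variety/stage keys sorted in ripening order when all names
#' follow the `<variety>_<stage>` convention.
#'
#' @param tbl Spectra tibble (see [read_spectra_csv()]).
#' @return Spectra tibble with one row per sample.
#' @export
average_replicates <- function(tbl) {
  wn <- spectra_wavenumbers(tbl)
  if (length(wn) == 0) abort("no wavenumber columns found")
  base <- stringr::str_remove(tbl$sample, "_r\\d+$")
  X <- spectra_matrix(tbl)
  groups <- split(seq_len(nrow(X)), base)
  avg <- t(vapply(groups, function(idx) colMeans(X[idx, , drop = FALSE]),
                  numeric(ncol(X))))
  keys <- names(groups)
  parts <- stringr::str_split_fixed(keys, "_", 2)
  if (all(parts[, 1] %in% variety_levels) &&
      all(parts[, 2] %in% stage_levels)) {
    ord <- order(factor(parts[, 1], levels = variety_levels),
                 factor(parts[, 2], levels = stage_levels))
  } else {
    ord <- order(keys)
  }
  rebuild_spectra(avg[ord, , drop = FALSE], wn,
                  tibble::tibble(sample = keys[ord]))
}

#' Attach the response to a spectra table
#'
#' Joins a `(sample, y)` table onto averaged spectra; every spectrum must
#' receive a response.
#'
#' @param tbl Spectra tibble.
#' @param response Tibble with columns `sample` and `y` (log10 mg/kg DW).
#' @return Spectra tibble with a `y` column.
#' @export
attach_response <- function(tbl, response) {
  miss <- setdiff(tbl$sample, response$sample)
  if (length(miss) > 0) {
    abort(paste0("no response for sample(s): ",
                 paste(head(miss, 5), collapse = ", ")))
  }
  y <- response$y[match(tbl$sample, response$sample)]
  wn_cols <- !is.na(suppressWarnings(as.numeric(names(tbl))))
  dplyr::bind_cols(tibble::tibble(sample = tbl$sample, y = y),
                   tbl[, wn_cols, drop = FALSE])
}

#' Restrict spectra to a wavenumber region
#'
#' Keeps the columns with `low <= wavenumber <= high` (both ends
#' inclusive). The modeling region defaults elsewhere to 752-1800 cm^-1,
#' the information-rich fingerprint window.
#'
#' @param tbl Spectra tibble.
#' @param low,high Region bounds, cm^-1.
#' @return Spectra tibble restricted to the region.
#' @export
select_region <- function(tbl, low = 752, high = 1800) {
  if (low >= high) abort("region must satisfy low < high")
  wn <- spectra_wavenumbers(tbl)
  keep <- wn[wn >= low & wn <= high]
  if (length(keep) == 0) abort("region selects no wavenumbers")
  X <- spectra_matrix(tbl)[, as.character(wn) %in% as.character(keep),
                           drop = FALSE]
  rebuild_spectra(X, keep, tbl)
}

#' Standard normal variate (row autoscaling)
#'
#' Transforms each spectrum to zero mean and unit sample standard
#' deviation across its wavenumbers: `(x - mean(x)) / sd(x)` per row, with
#' the n-1 standard deviation. This removes additive baseline offsets and
#' multiplicative intensity differences between spectra exactly.
#'
#' @param tbl Spectra tibble with >= 2 wavenumber columns.
#' @return SNV-transformed spectra tibble.
#' @export
snv <- function(tbl) {
  X <- spectra_matrix(tbl)
  if (ncol(X) < 2) abort("SNV needs at least 2 wavenumbers")
  s <- apply(X, 1, sd)
  if (any(s == 0)) {
    abort(paste0("constant spectrum, SNV undefined: ",
                 paste(tbl$sample[s == 0], collapse = ", ")))
  }
  Xs <- (X - rowMeans(X)) / s
  rebuild_spectra(Xs, spectra_wavenumbers(tbl), tbl)
}

#' Savitzky-Golay derivative filtering
#'
#' Applies the Savitzky-Golay local-polynomial derivative filter to each
#' spectrum. Defaults follow common second-derivative practice: 7-point
#' symmetric window, second-order polynomial, second derivative. Edge
#' points where the full window does not fit are dropped and the
#' wavenumber axis trimmed accordingly (`p_out = p - window + 1`); no edge
#' values are extrapolated. The derivative uses the unit point-spacing
#' convention (per index step); pass `delta` (the grid step in cm^-1) to
#' obtain physical per-cm^-1 units instead.
#'
#' @param tbl Spectra tibble.
#' @param window Odd window length (points), `> polyorder`.
#' @param polyorder Polynomial order of the local fit.
#' @param deriv Derivative order, `<= polyorder`.
#' @param delta Optional grid spacing for physical-unit scaling.
#' @return Spectra tibble with a trimmed axis.
#' @export
sg_derivative <- function(tbl, window = 7, polyorder = 2, deriv = 2,
                          delta = NULL) {
  if (window %% 2 != 1) abort("window must be odd")
  if (polyorder >= window) abort("polyorder must be < window")
  if (deriv > polyorder) abort("deriv must be <= polyorder")
  X <- spectra_matrix(tbl)
  p <- ncol(X)
  if (p < window) abort("fewer wavenumbers than the filter window")
  # central row of the SG projection matrix = convolution kernel
  # (includes the m! derivative factor)
  Fm <- signal::sgolay(p = polyorder, n = window, m = deriv)
  kern <- Fm[(window + 1) / 2, ]
  if (!is.null(delta)) kern <- kern / delta^deriv
  half <- (window - 1) / 2
  idx <- (half + 1):(p - half)
  out <- t(apply(X, 1, function(row) {
    vapply(idx, function(i) sum(kern * row[(i - half):(i + half)]),
           numeric(1))
  }))
  rebuild_spectra(out, spectra_wavenumbers(tbl)[idx], tbl)
}

#' Column mean centering
#'
#' Subtracts the column means of the spectral block (and the mean of `y`,
#' when present), returning the means so later predictions can apply the
#' same centering.
#'
#' @param tbl Spectra tibble (optionally with `y`).
#' @return List with `data` (centered spectra tibble), `column_means`
#'   (named numeric) and `y_mean` (`NA` if no response column).
#' @export
mean_center <- function(tbl) {
  X <- spectra_matrix(tbl)
  if (nrow(X) < 2) abort("mean centering needs >= 2 samples")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  out <- rebuild_spectra(Xc, spectra_wavenumbers(tbl), tbl)
  y_mean <- NA_real_
  if ("y" %in% names(out)) {
    y_mean <- mean(out$y)
    out$y <- out$y - y_mean
  }
  list(data = out, column_means = mu, y_mean = y_mean)
}

#' Random calibration/test split
#'
#' Draws a reproducible random partition of `n` samples into a calibration
#' set of size `floor(fraction * n)` and a test set of the remainder.
#'
#' @param n Number of samples (>= 4).
#' @param fraction Calibration fraction in (0, 1); default 0.75.
#' @param seed Integer seed; the split is a pure function of `(n, fraction,
#'   seed)` and does not disturb the global random state.
#' @return List with integer index vectors `calibration` and `test`.
#' @export
split_calibration_test <- function(n, fraction = 0.75, seed) {
  if (fraction <= 0 || fraction >= 1) abort("fraction must be in (0, 1)")
  if (n < 4) abort("need at least 4 samples to split")
  n_cal <- floor(fraction * n)
  if (n_cal == 0 || n_cal == n) abort("split leaves an empty subset")
  cal <- with_seed(seed, sort(sample.int(n, n_cal)))
  list(calibration = cal, test = setdiff(seq_len(n), cal))
}

# evaluate expr under a local RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Venetian-blinds cross-validation folds
#'
#' Systematic interleaved fold assignment: in row order, sample `i`
#' (counting from 0) joins fold `i mod n_segments`.
#'
#' @param n Number of samples.
#' @param n_segments Number of folds, `2 <= n_segments <= n`.
#' @return Integer fold index per sample, values `1..n_segments`.
#' @export
venetian_blinds <- function(n, n_segments) {
  if (n_segments < 2 || n_segments > n) {
    abort("n_segments must be between 2 and n")
  }
  ((seq_len(n) - 1L) %% n_segments) + 1L
}
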