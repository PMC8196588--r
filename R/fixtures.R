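#' Reference data tables shipped with the package
#'
#' `load_table1()` returns the glycoalkaloid concentrations (alpha-tomatine,
#' dehydrotomatine and their sum "tomatine", mg/kg dry weight, with standard
#' deviations) measured by HPLC-ESI-QqQ-MS/MS on eight industrial tomato
#' varieties across ripening stages. `load_table2()` returns the
#' thermogravimetric weight losses (percent, two temperature ranges) for the
#' same samples; the single red-stage sample has no thermogravimetric row.
#' `load_table3()` returns the mid-infrared band assignments used to seed the
#' spectral simulator, and `load_table4()` the reference-versus-predicted
#' comparison table.
#'
#' Each loader validates the fixture strictly: row counts, positivity,
#' internal consistency of the tomatine sums (within 2 mg/kg rounding slack)
#' and the below-detection dehydrotomatine entry, which is stored as `NA`
#' rather than zero.
#'
#' @return A tibble; one row per variety-by-stage sample (tables 1, 2, 4) or
#'   per band (table 3).
#' @name fixtures
NULL

fixture_path <- function(file) {
  path <- system.file("extdata", file, package = "tomachem")
  if (identical(path, "")) {
    abort(paste0("fixture file not found in installed package: ", file))
  }
  path
}

read_fixture <- function(file, col_types) {
  path <- fixture_path(file)
  out <- tryCatch(
    readr::read_csv(path, col_types = col_types, progress = FALSE),
    error = function(e) abort(paste0("corrupt fixture ", file, ": ",
                                     conditionMessage(e)))
  )
  out
}

check_sample_keys <- function(tbl, file) {
  bad <- !tbl$variety %in% variety_levels | !tbl$stage %in% stage_levels
  if (any(bad)) {
    abort(paste0(file, ": unknown variety/stage at row ",
                 paste(which(bad), collapse = ", ")))
  }
  invisible(tbl)
}

#' @rdname fixtures
#' @export
load_table1 <- function() {
  tbl <- read_fixture("table1_glycoalkaloids.csv", "ccdddddd")
  check_sample_keys(tbl, "table1_glycoalkaloids.csv")
  if (nrow(tbl) != 23L) {
    abort("table1_glycoalkaloids.csv: expected 23 rows")
  }
  conc <- c(tbl$alpha_tomatine, tbl$tomatine, tbl$dehydrotomatine)
  if (any(conc <= 0, na.rm = TRUE)) {
    abort("table1_glycoalkaloids.csv: non-positive concentration")
  }
  sds <- c(tbl$alpha_tomatine_sd, tbl$dehydrotomatine_sd, tbl$tomatine_sd)
  if (any(sds < 0, na.rm = TRUE)) {
    abort("table1_glycoalkaloids.csv: negative standard deviation")
  }
  both <- !is.na(tbl$dehydrotomatine)
  gap <- abs(tbl$tomatine - (tbl$alpha_tomatine + tbl$dehydrotomatine))[both]
  if (any(gap > 2)) {
    abort("table1_glycoalkaloids.csv: tomatine differs from component sum by > 2 mg/kg")
  }
  order_samples(tbl)
}

#' @rdname fixtures
#' @export
load_table2 <- function() {
  tbl <- read_fixture("table2_tga.csv", "ccdddd")
  check_sample_keys(tbl, "table2_tga.csv")
  if (nrow(tbl) != 22L || any(tbl$stage == "red")) {
    abort("table2_tga.csv: expected 22 rows with no red stage")
  }
  validate_tga(tbl)
  order_samples(tbl)
}

#' @rdname fixtures
#' @export
load_table3 <- function() {
  tbl <- read_fixture("table3_bands.csv", "dc")
  if (any(tbl$wavenumber < 752 | tbl$wavenumber > 1800)) {
    abort("table3_bands.csv: wavenumber outside 752-1800 cm^-1")
  }
  tbl
}

#' @rdname fixtures
#' @export
load_table4 <- function() {
  tbl <- read_fixture("table4_predictions.csv", "ccdddd")
  check_sample_keys(tbl, "table4_predictions.csv")
  vals <- c(tbl$reference, tbl$predicted_tga_mlr, tbl$predicted_ftir_pls)
  if (any(vals <= 0)) abort("table4_predictions.csv: non-positive value")
  order_samples(tbl)
}

validate_tga <- function(tbl, file = "table2_tga.csv") {
  bad <- tbl$wl_120_200 <= 0 | tbl$wl_120_200 >= 100 |
    tbl$wl_200_400 <= 0 | tbl$wl_200_400 >= 100 |
    tbl$wl_120_200 + tbl$wl_200_400 >= 100
  if (any(bad)) {
    abort(paste0(file, ": weight-loss invariant violated at row ",
                 paste(which(bad), collapse = ", "),
                 " (columns wl_120_200/wl_200_400)"))
  }
  invisible(tbl)
}

order_samples <- function(tbl) {
  dplyr::arrange(tbl,
                 factor(.data$variety, levels = variety_levels),
                 factor(.data$stage, levels = stage_levels))
}

#' Assemble the thermogravimetric calibration table
#'
#' Joins the glycoalkaloid reference concentrations with the
#' thermogravimetric features and builds the modeling response
#' `y = log10(tomatine)`. The response always uses the printed tomatine
#' column, never a recomputed alpha + dehydro sum. Samples named in
#' `exclude` (e.g. the red-stage leverage outlier `"H7204_red"`) are
#' dropped after the join.
#'
#' @param glyco Tibble from [load_table1()] (or same schema).
#' @param tga Tibble from [load_table2()] (or same schema).
#' @param exclude Character vector of `"<variety>_<stage>"` keys to drop.
#' @return Tibble with columns `variety`, `stage`, `x1` (weight loss percent,
#'   120-200 C), `x2` (200-400 C), `tomatine` (mg/kg DW) and `y`
#'   (log10 mg/kg DW), one row per calibration sample.
#' @examples
#' cal <- assemble_calibration_set(load_table1(), load_table2())
#' nrow(cal)  # 22
#' @export
assemble_calibration_set <- function(glyco, tga, exclude = "H7204_red") {
  if (length(exclude) > 0) {
    keys <- strsplit(exclude, "_", fixed = TRUE)
    ok <- vapply(keys, function(k) {
      length(k) == 2 && k[1] %in% variety_levels && k[2] %in% stage_levels
    }, logical(1))
    if (!all(ok)) {
      abort(paste0("invalid exclude key: ",
                   paste(exclude[!ok], collapse = ", ")))
    }
  }
  joined <- dplyr::inner_join(
    dplyr::select(glyco, "variety", "stage", "tomatine"),
    dplyr::select(tga, "variety", "stage", "wl_120_200", "wl_200_400"),
    by = c("variety", "stage")
  )
  joined <- dplyr::filter(
    joined,
    !paste(.data$variety, .data$stage, sep = "_") %in% .env$exclude
  )
  if (nrow(joined) == 0) abort("calibration join produced 0 rows")
  if (any(joined$tomatine <= 0)) {
    abort("non-positive tomatine: log10 response undefined")
  }
  out <- dplyr::transmute(
    joined,
    variety = .data$variety,
    stage = .data$stage,
    x1 = .data$wl_120_200,
    x2 = .data$wl_200_400,
    tomatine = .data$tomatine,
    y = log10(.data$tomatine)
  )
  order_samples(out)
}

#' Read and write typed sample tables
#'
#' Strict CSV I/O for the tabular schemas the pipeline touches (comma
#' separator, `.` decimal, header row required). `schema` picks the
#' validation applied after reading: `"tga"` enforces the weight-loss
#' invariants (each percentage in (0, 100), sum below 100), `"glyco"`
#' enforces positive concentrations, and `"none"` reads any CSV untouched.
#' Unknown extra columns are preserved. Violations report the offending
#' column and row.
#'
#' @param path File path.
#' @param schema One of `"tga"`, `"glyco"`, `"none"`.
#' @param records Tibble to write.
#' @return `read_sample_table()` returns a tibble; `write_sample_table()`
#'   returns `path` invisibly.
#' @export
read_sample_table <- function(path, schema = c("none", "tga", "glyco")) {
  schema <- match.arg(schema)
  tbl <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  if (schema == "tga") {
    need <- c("variety", "stage", "wl_120_200", "wl_200_400")
    miss <- setdiff(need, names(tbl))
    if (length(miss) > 0) {
      abort(paste0(path, ": missing column(s) ", paste(miss, collapse = ", ")))
    }
    if (nrow(tbl) > 0) validate_tga(tbl, file = path)
  } else if (schema == "glyco") {
    need <- c("variety", "stage", "tomatine")
    miss <- setdiff(need, names(tbl))
    if (length(miss) > 0) {
      abort(paste0(path, ": missing column(s) ", paste(miss, collapse = ", ")))
    }
    if (nrow(tbl) > 0 && any(tbl$tomatine <= 0, na.rm = TRUE)) {
      abort(paste0(path, ": non-positive tomatine at row ",
                   paste(which(tbl$tomatine <= 0), collapse = ", ")))
    }
  }
  tbl
}

#' @rdname read_sample_table
#' @export
write_sample_table <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Ratio of analyte concentrations between two samples
#'
#' Expresses one sample's analyte content as a percentage of another's,
#' e.g. the residual alpha-tomatine of a red-ripe fruit relative to the
#' green fruit of the same variety.
#'
#' @param glyco Glycoalkaloid tibble ([load_table1()] schema).
#' @param numerator,denominator `"<variety>_<stage>"` sample keys.
#' @param analyte Column name: `"alpha_tomatine"`, `"dehydrotomatine"` or
#'   `"tomatine"`.
#' @return Percentage, rounded to 1 decimal place.
#' @examples
#' concentration_ratio(load_table1(), "H7204_red", "H7204_green",
#'                     "alpha_tomatine")  # 1.3
#' @export
concentration_ratio <- function(glyco, numerator, denominator,
                                analyte = "tomatine") {
  pick <- function(key) {
    k <- strsplit(key, "_", fixed = TRUE)[[1]]
    row <- dplyr::filter(glyco, .data$variety == k[1], .data$stage == k[2])
    if (nrow(row) != 1) abort(paste0("sample not found: ", key))
    row[[analyte]]
  }
  num <- pick(numerator)
  den <- pick(denominator)
  if (is.na(num) || is.na(den)) abort("analyte missing (below LOD) for ratio")
  if (den == 0) abort("zero denominator concentration")
  round(100 * num / den, 1)
}
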