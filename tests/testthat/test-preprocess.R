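# small spectra tibble builders
make_spectra <- function(X, wn, samples) {
  out <- tibble::as_tibble(X, .name_repair = "minimal")
  names(out) <- as.character(wn)
  dplyr::bind_cols(tibble::tibble(sample = samples), out)
}

test_that("replicate averaging collapses to one row per sample", {
  wn <- seq(1000, 1018, 2)
  a <- sin(seq_along(wn))
  b <- cos(seq_along(wn))
  tbl <- make_spectra(rbind(a, a, a, b, 2 * b),
                      wn, c("s01_r1", "s01_r2", "s01_r3", "s02_r1", "s02_r2"))
  avg <- average_replicates(tbl)
  expect_equal(nrow(avg), 2)
  expect_equal(unname(spectra_matrix(avg)["s01", ]), a)
  expect_equal(unname(spectra_matrix(avg)["s02", ]), 1.5 * b)
})

test_that("averaging the default synthetic layout yields 22 sample rows", {
  ds <- generate_spectra_dataset(seed = 2)
  avg <- average_replicates(ds$spectra)
  expect_equal(nrow(avg), 22)
  expect_equal(spectra_wavenumbers(avg), seq(752, 1800, 2))
})

test_that("region selection is inclusive and counts grid points", {
  wn <- seq(700, 1900, 2)
  tbl <- make_spectra(matrix(rnorm(2 * length(wn)), 2), wn, c("a", "b"))
  sel <- select_region(tbl, 752, 1800)
  kept <- spectra_wavenumbers(sel)
  expect_equal(min(kept), 752)
  expect_equal(max(kept), 1800)
  expect_equal(length(kept), floor((1800 - 752) / 2) + 1)
  # full-axis region is the identity
  expect_equal(select_region(tbl, 700, 1900), tbl)
  expect_error(select_region(tbl, 2000, 2100), "must satisfy|no wavenumbers")
})

test_that("snv standardizes every row with the sample sd", {
  tbl <- make_spectra(matrix(c(1, 2, 3), 1), c(10, 20, 30), "s1")
  expect_equal(unname(spectra_matrix(snv(tbl))[1, ]), c(-1, 0, 1))

  set.seed(3)
  r <- make_spectra(matrix(rnorm(5 * 20), 5), seq(2, 40, 2), paste0("s", 1:5))
  out <- spectra_matrix(snv(r))
  expect_true(all(abs(rowMeans(out)) < 1e-12))
  expect_equal(unname(apply(out, 1, sd)), rep(1, 5), tolerance = 1e-12)
  # idempotent on already-normalized rows
  expect_equal(snv(snv(r)), snv(r), tolerance = 1e-12)

  const <- make_spectra(matrix(1, 1, 4), 1:4 * 10, "flat")
  expect_error(snv(const), "flat")
})

test_that("savitzky-golay derivative is exact on low-order polynomials", {
  wn <- seq(1, 40)
  quad <- make_spectra(matrix(wn^2, 1), wn, "q")
  d2 <- spectra_matrix(sg_derivative(quad, 7, 2, 2))
  expect_equal(unname(d2[1, ]), rep(2, 34), tolerance = 1e-10)

  lin <- make_spectra(matrix(3 * wn + 1, 1), wn, "l")
  d2l <- spectra_matrix(sg_derivative(lin, 7, 2, 2))
  expect_equal(unname(d2l[1, ]), rep(0, 34), tolerance = 1e-10)
})

test_that("savitzky-golay equals the local polynomial-fit oracle", {
  set.seed(8)
  row <- rnorm(30)
  tbl <- make_spectra(matrix(row, 1), seq_len(30), "r")
  for (cfg in list(c(7, 2, 2), c(7, 2, 1), c(9, 3, 2))) {
    got <- spectra_matrix(sg_derivative(tbl, cfg[1], cfg[2], cfg[3]))[1, ]
    expect_equal(unname(got),
                 sg_polyfit_oracle(row, cfg[1], cfg[2], cfg[3]),
                 tolerance = 1e-8)
  }
})

test_that("savitzky-golay trims the axis and interpolates at full order", {
  set.seed(9)
  tbl <- make_spectra(matrix(rnorm(2 * 25), 2), seq(752, 800, 2),
                      c("a", "b"))
  out <- sg_derivative(tbl, 7, 2, 2)
  expect_equal(length(spectra_wavenumbers(out)), 25 - 7 + 1)
  expect_equal(spectra_wavenumbers(out), seq(758, 794, 2))
  # deriv 0 at polyorder window-1 reproduces interior points
  smooth0 <- sg_derivative(tbl, 7, 6, 0)
  expect_equal(unname(spectra_matrix(smooth0)),
               unname(spectra_matrix(tbl)[, 4:22]), tolerance = 1e-8)
  expect_error(sg_derivative(tbl, 8, 2, 2), "odd")
  expect_error(sg_derivative(tbl, 7, 2, 3), "deriv")
})

test_that("preprocessing commutes with row permutation and keeps duplicates", {
  set.seed(10)
  wn <- seq(752, 900, 2)
  X <- matrix(rnorm(4 * length(wn)), 4)
  X[4, ] <- X[1, ]
  tbl <- make_spectra(X, wn, paste0("s", 1:4))
  chain <- function(t) sg_derivative(snv(select_region(t, 760, 890)), 7, 2, 2)
  out <- chain(tbl)
  # duplicated inputs give duplicated outputs
  expect_equal(unname(spectra_matrix(out)[4, ]),
               unname(spectra_matrix(out)[1, ]))
  perm <- tbl[c(3, 1, 4, 2), ]
  out_perm <- chain(perm)
  expect_equal(spectra_matrix(out_perm)[order(perm$sample), ],
               spectra_matrix(out)[order(tbl$sample), ])
  # purity: the input tibble is untouched
  expect_equal(unname(spectra_matrix(tbl)), unname(X))
})

test_that("mean centering returns reusable means and inverts", {
  set.seed(11)
  tbl <- make_spectra(matrix(rnorm(6 * 10), 6), seq(20, 38, 2),
                      paste0("s", 1:6))
  tbl <- dplyr::mutate(tbl, y = rnorm(6), .after = "sample")
  mc <- mean_center(tbl)
  Xc <- spectra_matrix(mc$data)
  expect_true(all(abs(colMeans(Xc)) < 1e-12))
  expect_lt(abs(mean(mc$data$y)), 1e-12)
  back <- sweep(Xc, 2, mc$column_means, `+`)
  expect_equal(unname(back), unname(spectra_matrix(tbl)))
  # re-centering a centered table changes nothing
  mc2 <- mean_center(mc$data)
  expect_equal(unname(mc2$column_means), rep(0, 10), tolerance = 1e-12)
})

test_that("calibration/test split is reproducible, disjoint and covering", {
  s <- split_calibration_test(22, 0.75, seed = 5)
  expect_length(s$calibration, 16)
  expect_length(s$test, 6)
  expect_length(intersect(s$calibration, s$test), 0)
  expect_setequal(c(s$calibration, s$test), 1:22)

  s2 <- split_calibration_test(4, 0.5, seed = 1)
  expect_length(s2$calibration, 2)
  expect_setequal(c(s2$calibration, s2$test), 1:4)

  expect_identical(split_calibration_test(22, 0.75, seed = 5), s)
  diff_seeds <- vapply(1:10, function(k) {
    !identical(split_calibration_test(22, 0.75, seed = k)$calibration,
               s$calibration)
  }, logical(1))
  expect_true(any(diff_seeds))
  expect_error(split_calibration_test(3, 0.75, seed = 1), "at least 4")
  expect_error(split_calibration_test(10, 1.2, seed = 1), "fraction")
})

test_that("venetian blinds interleave samples into covering folds", {
  f <- venetian_blinds(6, 3)
  expect_equal(which(f == 1), c(1, 4))
  expect_equal(which(f == 2), c(2, 5))
  expect_equal(which(f == 3), c(3, 6))
  expect_equal(venetian_blinds(4, 2), c(1L, 2L, 1L, 2L))
  for (n in c(5, 11, 17, 30)) {
    for (s in 2:min(n, 6)) {
      f <- venetian_blinds(n, s)
      expect_setequal(sort(unique(f)), seq_len(s))
      expect_equal(length(f), n)
      expect_true(all(tabulate(f) >= 1))
    }
  }
  expect_error(venetian_blinds(3, 5), "between 2 and n")
})

test_that("spectra CSV io round-trips through the wavenumber-first layout", {
  ds <- generate_spectra_dataset(n_samples = 4, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds$spectra, path)
  back <- read_spectra_csv(path)
  expect_equal(back$sample, ds$spectra$sample)
  expect_equal(unname(spectra_matrix(back)),
               unname(spectra_matrix(ds$spectra)), tolerance = 1e-12)
})
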