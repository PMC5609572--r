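# reference calibration used across tests: a plausible EBT3-like cubic
ref_curve <- function() {
  cf <- c(0, 8.0, 6.0, 4.0)          # dose(x) = 8x + 6x^2 + 4x^3
  nods <- seq(0.03, 0.55, length.out = 9)
  doses <- cf[2] * nods + cf[3] * nods^2 + cf[4] * nods^3
  fit_calibration(nods, doses)
}

test_that("netOD is the log ratio of unexposed to exposed intensity", {
  expect_equal(net_od(40000, 40000), 0)
  expect_equal(net_od(4000, 40000), 1)
  m <- matrix(c(1000, 2000, 4000, 8000, 16000, 32000, 40000, 20000, 10000), 3)
  elementwise <- matrix(vapply(as.vector(m), net_od,
                               unexposed_intensity = 40000, numeric(1)), 3)
  expect_equal(net_od(m, 40000), elementwise)
  expect_error(net_od(0, 40000), "positive")
  # invariant under a common intensity rescale
  expect_equal(net_od(1234 * 0.37, 40000 * 0.37), net_od(1234, 40000))
})

test_that("an exact cubic is recovered to 1e-9", {
  cf <- c(0, 7.5, 5.2, 3.1)
  nods <- seq(0.05, 0.6, length.out = 12)
  doses <- cf[2] * nods + cf[3] * nods^2 + cf[4] * nods^3
  fit <- fit_calibration(nods, doses)
  expect_equal(unname(fit$coefficients), cf, tolerance = 1e-9)
  expect_lt(fit$fit_residual_rms, 1e-9)
  # with a free intercept
  cf4 <- c(0.2, 7.5, 5.2, 3.1)
  doses4 <- cf4[1] + cf4[2] * nods + cf4[3] * nods^2 + cf4[4] * nods^3
  fit4 <- fit_calibration(nods, doses4, constrain_origin = FALSE)
  expect_equal(unname(fit4$coefficients), cf4, tolerance = 1e-9)
})

test_that("origin constraint pins dose to zero at netOD zero", {
  nods <- c(0, seq(0.1, 0.5, length.out = 6))
  doses <- 2 * nods + 0.5 * nods^2
  fit <- fit_calibration(nods, doses)
  expect_identical(unname(fit$coefficients[1]), 0)
  expect_equal(calibration_dose(fit, 0), 0)
})

test_that("duplicated calibration points do not move the fit", {
  nods <- seq(0.05, 0.5, length.out = 8)
  doses <- 8 * nods + 5 * nods^2 + 3 * nods^3
  a <- fit_calibration(nods, doses)
  b <- fit_calibration(c(nods, nods), c(doses, doses))
  expect_equal(a$coefficients, b$coefficients, tolerance = 1e-9)
  # normal-equations oracle
  X <- cbind(nods, nods^2, nods^3)
  oracle <- solve(crossprod(X), crossprod(X, doses))
  expect_equal(unname(a$coefficients[2:4]), as.vector(oracle), tolerance = 1e-9)
})

test_that("non-monotone fits are refused with guidance", {
  nods <- seq(0, 1, length.out = 9)
  doses <- sin(6 * nods)
  expect_error(fit_calibration(nods, doses), "increasing")
  expect_error(fit_calibration(1:3 / 10, 1:3), "at least 5")
})

test_that("a uniform exposure maps back to a uniform dose", {
  curve <- ref_curve()
  scan <- synthetic_film_scan(matrix(2, 12, 12), curve, noise_sigma = 0)
  map <- dose_map(scan, curve)
  expect_equal(as.vector(map$dose), rep(2, 144), tolerance = 1e-3)
  # background-only film reads zero dose
  blank <- film_scan(matrix(40000, 5, 5), 300, 40000)
  expect_equal(dose_map(blank, curve)$dose, matrix(0, 5, 5))
})

test_that("dose maps round-trip within the fit residual plus digitization", {
  curve <- ref_curve()
  for (D in c(0.3, 1, 2.5, 3.9)) {
    scan <- synthetic_film_scan(matrix(D, 6, 6), curve, noise_sigma = 0)
    got <- mean(dose_map(scan, curve)$dose)
    # one intensity count at this exposure corresponds to this dose step
    inten <- 40000 * 10^(-calibration_netod(curve, D))
    digi <- abs(calibration_dose(curve, net_od(inten - 1, 40000)) -
                calibration_dose(curve, net_od(inten, 40000)))
    expect_lt(abs(got - D), curve$fit_residual_rms + digi)
  }
})

test_that("doses beyond the calibrated range are flagged, not clipped", {
  curve <- ref_curve()
  hot <- synthetic_film_scan(matrix(c(2, 2, 2, 6), 2, 2), curve,
                             noise_sigma = 0)
  expect_warning(map <- dose_map(hot, curve), "above the calibrated")
  expect_equal(sum(map$out_of_range), 1)
  expect_gt(max(map$dose), 4)   # preserved, not clipped
})

test_that("film matrix files and TIFFs round-trip", {
  curve <- ref_curve()
  scan <- synthetic_film_scan(matrix(runif(30, 0.5, 3), 5, 6), curve,
                              dpi = 150, seed = 7)
  f <- withr::local_tempfile(fileext = ".txt")
  write_film_matrix(scan, f)
  back <- read_film_matrix(f)
  expect_equal(back$pixel_matrix, scan$pixel_matrix, ignore_attr = TRUE)
  expect_equal(back$dpi, 150)
  skip_if_not_installed("tiff")
  ftif <- withr::local_tempfile(fileext = ".tif")
  write_film_tiff(scan, ftif)
  back2 <- read_film_tiff(ftif, dpi = 150)
  expect_equal(back2$pixel_matrix, scan$pixel_matrix, ignore_attr = TRUE)
})

test_that("a synthetic circular field measures its own diameter end to end", {
  curve <- ref_curve()
  pitch <- 25.4 / 150
  half_n <- ceiling(20 / pitch)
  ax <- (seq_len(2 * half_n + 1) - (half_n + 1)) * pitch
  r <- sqrt(outer(ax^2, ax^2, `+`))
  dose <- 2 * 0.5 * (1 - pracma::erf((r - 12.5) / (0.5 * sqrt(2))))
  scan <- synthetic_film_scan(dose, curve, dpi = 150, seed = 3)
  map <- dose_map(scan, curve)
  prof <- dose_profile(map, axis = "x")
  m <- extract_lateral_metrics(prof)
  expect_equal(m$field_size_w50, 25, tolerance = 0.2 / 25)
  expect_equal(extract_lateral_metrics(dose_profile(map, "y"))$field_size_w50,
               25, tolerance = 0.2 / 25)
})
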