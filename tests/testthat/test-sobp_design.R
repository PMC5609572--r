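test_that("modulator specs enforce the step contract", {
  s <- modulator_spec(c(0, 0.8), c(0.6, 0.4))
  expect_s3_class(s, "modulator_spec")
  expect_error(modulator_spec(c(0.8, 0), c(0.5, 0.5)), "first step")
  expect_error(modulator_spec(c(0, -1), c(0.5, 0.5)), "non-negative")
  expect_error(modulator_spec(c(0, 1), c(0.5, -0.5)), "non-negative")
  expect_warning(s2 <- modulator_spec(c(0, 1), c(0.50, 0.48)), "renormaliz")
  expect_equal(sum(s2$steps$weight), 1)
})

test_that("modulator files parse and round-trip bit-exactly", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "mode: absolute", "0 0.05", "0.8 0.10"), f)
  s <- read_modulator(f)
  expect_equal(nrow(s$steps), 2)
  expect_identical(s$steps$thickness[1], 0)      # air gap
  expect_identical(s$weight_mode, "absolute")

  ten <- modulator_spec(c(0, seq(0.7, 6.3, by = 0.7)),
                        runif(10), weight_mode = "absolute")
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_modulator(ten, f2)
  back <- read_modulator(f2)
  expect_identical(back$steps, ten$steps)
  expect_identical(back$weight_mode, ten$weight_mode)

  f3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("mode: relative", "0 0.5", "1 0.48"), f3)
  expect_warning(s3 <- read_modulator(f3), "renormaliz")
  expect_equal(sum(s3$steps$weight), 1)

  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("mode: relative", "0 0.5", "1 bad"), f4)
  expect_error(read_modulator(f4), "line 3")
})

test_that("superposition is the weighted sum of its component peaks", {
  fam <- sobp_peak_family(62, 3, step_mm = 2)
  # identity: a single step with weight 1
  one <- synthesize_sobp(fam[1], modulator_spec(0, 1, "absolute"))
  expect_identical(one$dose, fam[[1]]$dose)
  # hand-computed weighted sum at sampled depths
  w <- c(0.7, 0.2, 0.1)
  spec <- modulator_spec(c(0, 2, 4), w, "absolute")
  sobp <- synthesize_sobp(fam, spec)
  idx <- c(10, 100, 200, 280, 320)
  by_hand <- w[1] * fam[[1]]$dose[idx] + w[2] * fam[[2]]$dose[idx] +
    w[3] * fam[[3]]$dose[idx]
  expect_equal(sobp$dose[idx], by_hand, tolerance = 1e-12)
  # linearity: doubling every weight doubles the dose point-wise
  dbl <- synthesize_sobp(fam, modulator_spec(c(0, 2, 4), 2 * w, "absolute"))
  expect_equal(dbl$dose, 2 * sobp$dose, tolerance = 1e-12)
  # a zero-weight step never changes the curve
  with0 <- synthesize_sobp(c(fam, fam[3]),
                           modulator_spec(c(0, 2, 4, 6), c(w, 0), "absolute"))
  expect_identical(with0$dose, sobp$dose)
})

test_that("grid mismatches are reported with the offending step", {
  fam <- sobp_peak_family(62, 2, step_mm = 2)
  odd <- pristine_bragg(50)
  expect_error(synthesize_sobp(list(fam[[1]], odd),
                               modulator_spec(c(0, 2), c(0.5, 0.5))),
               "peak 2")
})

test_that("weight optimization matches the independent NNLS oracle", {
  fam <- sobp_peak_family(62, 6, step_mm = 0.9)
  zpk <- fam[[1]]$depth_grid[which.max(fam[[1]]$dose)]
  spec <- design_weights(fam, zpk - 4.5, zpk, tolerance = 0.05)
  z <- fam[[1]]$depth_grid
  rows <- which(z >= zpk - 4.5 & z <= zpk)
  A <- vapply(fam, function(p) p$dose[rows], numeric(length(rows)))
  oracle <- pracma::lsqnonneg(A, rep(1, length(rows)))$x
  expect_equal(spec$steps$weight, oracle / sum(oracle), tolerance = 1e-8)
  expect_identical(spec$weight_mode, "relative")
  expect_true(all(spec$steps$weight >= 0))
})

test_that("the optimizer is within 5% of an exhaustive lattice search", {
  fam <- sobp_peak_family(62, 3, step_mm = 1.2)
  zpk <- fam[[1]]$depth_grid[which.max(fam[[1]]$dose)]
  z <- fam[[1]]$depth_grid
  rows <- which(z >= zpk - 2.4 & z <= zpk)
  A <- vapply(fam, function(p) p$dose[rows], numeric(length(rows)))
  b <- rep(1, length(rows))
  w_opt <- protonQA:::.nnls(A, b)
  obj <- function(w) sum((A %*% w - b)^2)
  lattice <- seq(0, 1.5, by = 0.05)
  best <- Inf
  for (w1 in lattice) for (w2 in lattice) {
    r0 <- b - A[, 1] * w1 - A[, 2] * w2
    v <- vapply(lattice, function(w3) sum((r0 - A[, 3] * w3)^2), numeric(1))
    best <- min(best, min(v))
  }
  expect_lte(obj(w_opt), best * 1.0001)        # true optimum beats the lattice
  expect_lte(obj(w_opt), best * 1.05)
})

test_that("the optimum never worsens as steps are added", {
  fam <- sobp_peak_family(62, 6, step_mm = 0.8)
  zpk <- fam[[1]]$depth_grid[which.max(fam[[1]]$dose)]
  z <- fam[[1]]$depth_grid
  rows <- which(z >= zpk - 3.5 & z <= zpk)
  b <- rep(1, length(rows))
  objs <- vapply(3:6, function(k) {
    A <- vapply(fam[1:k], function(p) p$dose[rows], numeric(length(rows)))
    sum((A %*% protonQA:::.nnls(A, b) - b)^2)
  }, numeric(1))
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("a single-peak design collapses to weight one", {
  pk <- pristine_bragg(62)
  zpk <- pk$depth_grid[which.max(pk$dose)]
  spec <- design_weights(list(pk), zpk - 0.3, zpk, tolerance = 0.2)
  expect_equal(spec$steps$weight, 1)
})

test_that("designed modulators flatten their region end to end", {
  # spacing ~2.5 sigma: fine enough for a 2% plateau
  fam <- sobp_peak_family(62, 10, step_mm = 0.8)
  zpk <- fam[[1]]$depth_grid[which.max(fam[[1]]$dose)]
  spec <- design_weights(fam, zpk - 7.2, zpk, tolerance = 0.02)
  expect_lte(attr(spec, "achieved_homogeneity"), 2)
  m <- extract_sobp_metrics(synthesize_sobp(fam, spec))
  expect_lte(m$homogeneity, 2)
  # the measured plateau width tracks the requested one within a peak FWHM
  expect_equal(m$sobp_width, 7.2, tolerance = peak_fwhm(fam[[1]]) / 7.2)
})

test_that("infeasible flatness requests fail with the achieved value", {
  fam <- sobp_peak_family(62, 4, step_mm = 3)
  zpk <- fam[[1]]$depth_grid[which.max(fam[[1]]$dose)]
  expect_error(design_weights(fam, zpk - 9, zpk, tolerance = 0.02),
               "achieved homogeneity")
})
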