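test_that("proton LET delegates to the water stopping power", {
  expect_equal(let_of(62), stopping_power(62, water, units = "keV.um"),
               tolerance = 1e-12)
  expect_equal(let_of(62), 1.0, tolerance = 0.15)
  E <- seq(30, 200, by = 5)
  expect_true(all(diff(let_of(E)) < 0))
  expect_error(let_of(62, charge = 0), "unknown species")
})

test_that("ion LET uses effective-charge scaling at equal velocity", {
  # an alpha at 4x the proton energy moves at the proton's velocity
  ratio <- let_of(248, charge = 2, mass_number = 4) / let_of(62)
  expect_gt(ratio, 3.9)   # z^2 = 4, Barkas screening only slightly below
  expect_lte(ratio, 4)
})

test_that("track and dose averages follow the moment formulas", {
  sp1 <- fluence_spectrum(1, data.frame(name = "p", charge = 1, mass_number = 1),
                          c(59, 65), array(1, c(1, 1, 1)))
  av <- average_let(sp1, 1)
  expect_equal(av$let_track, av$let_dose)
  expect_equal(av$let_track, let_of(62), tolerance = 1e-12)

  # two occupied bins, equal fluence: track = mean(S), dose = sum(S^2)/sum(S)
  edges <- c(10, 14, 100, 140)
  sp2 <- fluence_spectrum(1, data.frame(name = "p", charge = 1, mass_number = 1),
                          edges, array(c(1, 0, 1), c(1, 1, 3)))
  S1 <- let_of(12); S2 <- let_of(120)
  av2 <- average_let(sp2, 1)
  expect_equal(av2$let_track, (S1 + S2) / 2, tolerance = 1e-12)
  expect_equal(av2$let_dose, (S1^2 + S2^2) / (S1 + S2), tolerance = 1e-12)
})

test_that("the vectorized average matches an unrolled brute-force sum", {
  set.seed(11)
  sp <- random_spectrum(n_depth = 2, n_species = 3, n_bins = 10)
  centres <- (sp$energy_bin_edges[-1] + sp$energy_bin_edges[-11]) / 2
  num_t <- den_t <- num_d <- 0
  for (is in 1:3) for (ib in 1:10) {
    S <- let_of(centres[ib], sp$species$charge[is], sp$species$mass_number[is])
    phi <- sp$counts[2, is, ib]
    den_t <- den_t + phi
    num_t <- num_t + phi * S
    num_d <- num_d + phi * S^2
  }
  av <- average_let(sp, 2)
  expect_equal(av$let_track, num_t / den_t, tolerance = 1e-12)
  expect_equal(av$let_dose, num_d / num_t, tolerance = 1e-12)
})

test_that("empty depths are rejected as undefined", {
  sp <- fluence_spectrum(1:2, data.frame(name = "p", charge = 1, mass_number = 1),
                         c(10, 20), array(c(1, 0), c(2, 1, 1)))
  expect_error(average_let(sp, 2), "zero total fluence")
  expect_error(average_let(sp, 99), "outside")
})

test_that("dose-averaged LET dominates track-averaged LET on random spectra", {
  set.seed(2024)
  for (i in 1:150) {
    sp <- random_spectrum(n_depth = 2, n_species = sample(1:3, 1),
                          n_bins = sample(3:12, 1))
    av <- average_let(sp, 1)
    expect_gte(av$let_dose, av$let_track)
  }
})

test_that("averages are invariant under uniform fluence rescaling and merge by concatenation", {
  set.seed(5)
  sp <- random_spectrum()
  scaled <- fluence_spectrum(sp$depth_bins, sp$species, sp$energy_bin_edges,
                             sp$counts * 137)
  expect_equal(average_let(scaled, 2), average_let(sp, 2), tolerance = 1e-12)
  # merging a spectrum with itself (doubled species list) changes nothing
  mc <- array(0, dim(sp$counts) + c(0, 2, 0))
  mc[, 1:2, ] <- sp$counts
  mc[, 3:4, ] <- sp$counts
  merged <- fluence_spectrum(sp$depth_bins, rbind(sp$species, sp$species),
                             sp$energy_bin_edges, mc)
  expect_equal(average_let(merged, 2), average_let(sp, 2), tolerance = 1e-12)
})

test_that("the primaries-only depth curve has the Bragg LET structure", {
  lc <- primaries_let_depth_curve(62, grid_step = 0.2)
  expect_equal(lc$let_dose[1], 1.0, tolerance = 0.15)
  expect_true(all(lc$let_dose >= lc$let_track - 1e-12))
  # LET rises monotonically through 95% of the range
  R <- csda_range(62, water, "mm")
  rising <- lc$depth <= 0.95 * R
  expect_true(all(diff(lc$let_track[rising]) > 0))
})

test_that("the zero-spread limit reduces to the closed form", {
  lc <- primaries_let_depth_curve(62, grid_step = 0.5, sigma_E = 0)
  expect_equal(lc$let_track[1], let_of(62), tolerance = 1e-9)
  R <- csda_range(62, water, "mm")
  Ez <- energy_at_residual_range(R - lc$depth, water, units = "mm")
  expect_equal(lc$let_track, let_of(Ez), tolerance = 1e-9)
  expect_equal(lc$let_dose, lc$let_track, tolerance = 1e-12)
})

test_that("injected secondaries raise the dose average and respect identities", {
  lowE <- function(E) as.numeric(E < 20)          # low-energy, high-LET component
  sp <- fluence_spectrum(1:3, data.frame(name = "p", charge = 1, mass_number = 1),
                         c(5, 15, 45, 70), array(c(rep(0, 3), rep(0, 3), rep(1, 3)),
                                                 c(3, 1, 3)))
  # zero relative fluence is the identity
  same <- inject_secondary_component(sp, data.frame(name = "p2", charge = 1,
                                                    mass_number = 1), 0, lowE)
  for (z in 1:3)
    expect_equal(average_let(same, z), average_let(sp, z), tolerance = 1e-12)
  # a high-LET admixture never lowers the dose average
  mixed <- inject_secondary_component(sp, data.frame(name = "alpha", charge = 2,
                                                     mass_number = 4), 0.1, lowE)
  for (z in 1:3) {
    expect_gte(average_let(mixed, z)$let_dose, average_let(sp, z)$let_dose)
  }
  # adding fluence with the identical stopping power leaves the track average alone
  clone <- inject_secondary_component(sp, data.frame(name = "p", charge = 1,
                                                     mass_number = 1), 0.5,
                                      function(E) as.numeric(E > 45))
  for (z in 1:3)
    expect_equal(average_let(clone, z)$let_track, average_let(sp, z)$let_track,
                 tolerance = 1e-12)
  # the original spectrum is untouched
  expect_equal(dim(sp$counts)[2], 1)
})

test_that("fluence spectrum files round-trip", {
  set.seed(8)
  sp <- random_spectrum(n_depth = 3, n_species = 2, n_bins = 5)
  f <- withr::local_tempfile(fileext = ".txt")
  write_fluence_spectrum(sp, f)
  back <- read_fluence_spectrum(f)
  expect_equal(back$depth_bins, sp$depth_bins)
  expect_equal(back$energy_bin_edges, sp$energy_bin_edges)
  expect_equal(back$counts, sp$counts)
  expect_equal(back$species$charge, sp$species$charge)
})
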