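#' Analytical pristine Bragg curve
#'
#' Builds a depth-dose curve in water for a monoenergetic proton beam from
#' the CSDA picture: the local dose is proportional to the stopping power at
#' the residual energy, `dose(z) ~ S(E(R0 - z))`, convolved with a Gaussian
#' range-straggling kernel and normalized to a peak value of 1. The kernel is
#' truncated at +/- 5 sigma, so the curve is exactly zero beyond
#' `range + 5 sigma`.
#'
#' @param E Beam energy in MeV (10-250).
#' @param grid_step Depth grid step in mm, at most 0.1 (the scan resolution
#'   the curve emulates).
#' @param straggling_factor Straggling scale: the kernel sigma is
#'   `straggling_factor * R^0.935` with R the CSDA range in mm (default 0.012,
#'   the classical parameterization of range straggling in water). A sigma
#'   below `grid_step` is clamped to `grid_step` with a warning.
#' @param grid_max Optional depth-grid upper end in mm; defaults to
#'   `range + 6 sigma + 1`. Use it to put several peaks on a common grid.
#' @param model Stopping-power model of the phantom (default water).
#' @return An object of class `pristine_peak` with fields `depth_grid` (mm),
#'   `dose` (a.u., peak 1), `nominal_energy`, `range90` (mm) and `sigma` (mm).
#' @examples
#' pk <- pristine_bragg(62)
#' pk$range90
#' @export
pristine_bragg <- function(E, grid_step = 0.1, straggling_factor = 0.012,
                           grid_max = NULL, model = water_model()) {
  if (E < 10 || E > 250) stop("beam energy must be within 10-250 MeV")
  if (grid_step <= 0 || grid_step > 0.1)
    stop("grid_step must be positive and at most 0.1 mm")
  R <- csda_range(E, model, units = "mm")
  sigma <- straggling_factor * R^0.935
  if (sigma < grid_step) {
    warning("straggling sigma below grid step; clamped to the grid step")
    sigma <- grid_step
  }
  if (is.null(grid_max)) grid_max <- R + 6 * sigma + 1
  z <- seq(0, grid_max, by = grid_step)
  res_r <- pmax(R - z, 0)                       # residual range, mm
  E_res <- energy_at_residual_range(res_r, model, units = "mm")
  raw <- numeric(length(z))
  live <- res_r > 0
  # protons below the supported energy edge deposit at the edge stopping power
  Eval <- pmax(E_res[live], .const$E_MIN)
  raw[live] <- stopping_power(Eval, model)
  # truncated Gaussian straggling kernel; replicate the entrance value below
  # the surface (the plateau continues upstream), zero beyond the far end
  half <- ceiling(5 * sigma / grid_step)
  k <- stats::dnorm(seq(-half, half) * grid_step, sd = sigma)
  k <- k / sum(k)
  full <- stats::convolve(c(rep(raw[1], half), raw, numeric(half)),
                          rev(k), type = "open")
  dose <- full[(2 * half + 1):(2 * half + length(z))]
  dose[dose < 0] <- 0
  dose <- dose / max(dose)
  structure(
    list(depth_grid = z, dose = dose, nominal_energy = E,
         range90 = .distal_crossing(z, dose, 0.9 * max(dose)),
         sigma = sigma, grid_step = grid_step,
         straggling_factor = straggling_factor),
    class = "pristine_peak")
}

#' @export
print.pristine_peak <- function(x, ...) {
  cat(sprintf("<pristine_peak> E = %g MeV  range90 = %.3f mm  sigma = %.3f mm  %d points\n",
              x$nominal_energy, x$range90, x$sigma, length(x$depth_grid)))
  invisible(x)
}

#' Pull a pristine peak back with a range shifter
#'
#' A uniform water-equivalent absorber upstream of the phantom reduces the
#' beam's residual range without modulating it: the shifted peak is generated
#' at the energy whose CSDA range is the original range minus the shifter
#' thickness.
#'
#' @param peak_source_energy Unshifted beam energy, MeV.
#' @param shifter_thickness Water-equivalent thickness in mm; must be smaller
#'   than the beam range.
#' @inheritParams pristine_bragg
#' @return A `pristine_peak`.
#' @export
apply_range_shifter <- function(peak_source_energy, shifter_thickness,
                                grid_step = 0.1, straggling_factor = 0.012,
                                grid_max = NULL, model = water_model()) {
  if (shifter_thickness < 0) stop("shifter thickness must be non-negative")
  if (shifter_thickness == 0)
    return(pristine_bragg(peak_source_energy, grid_step, straggling_factor,
                          grid_max, model))
  R <- csda_range(peak_source_energy, model, units = "mm")
  if (shifter_thickness >= R)
    stop(sprintf("beam fully stopped: shifter %g mm >= range %.3f mm",
                 shifter_thickness, R))
  E_out <- energy_at_residual_range(R - shifter_thickness, model, units = "mm")
  if (E_out < 10)
    stop("beam fully stopped: residual energy below the 10 MeV model floor")
  pristine_bragg(E_out, grid_step, straggling_factor, grid_max, model)
}

#' Lateral beam-profile model
#'
#' Parameters of the synthetic transverse dose profile of a flat scattered
#' field: a flat top with error-function shoulders, an optional one-sided
#' scale asymmetry and optional seeded multiplicative noise.
#'
#' @param field_radius Half-width `a` of the flat top, mm.
#' @param penumbra_sigma Gaussian edge sigma, mm (the 80-20 penumbra of an
#'   isolated edge is `1.683 * sigma`).
#' @param asymmetry_factor Multiplicative scale applied to the `x > 0` side
#'   (1 = symmetric field).
#' @param noise_sigma Relative sigma of multiplicative Gaussian noise
#'   (0 = noiseless).
#' @param seed Integer seed used when `noise_sigma > 0`.
#' @return An object of class `lateral_profile_model`.
#' @export
lateral_profile_model <- function(field_radius, penumbra_sigma,
                                  asymmetry_factor = 1, noise_sigma = 0,
                                  seed = 1L) {
  if (field_radius <= 0) stop("field_radius must be positive")
  if (penumbra_sigma <= 0) stop("penumbra_sigma must be positive")
  if (asymmetry_factor <= 0) stop("asymmetry_factor must be positive")
  structure(list(field_radius = field_radius, penumbra_sigma = penumbra_sigma,
                 asymmetry_factor = asymmetry_factor, noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "lateral_profile_model")
}

#' Synthetic lateral dose profile
#'
#' Evaluates the flat-top/erf-shoulder profile
#' `D(x) = 0.5 * (erf((x + a) / (sigma sqrt 2)) - erf((x - a) / (sigma sqrt 2)))`
#' on a uniform position grid, scales the `x > 0` side by the asymmetry
#' factor and applies seeded multiplicative noise when requested. The global
#' RNG state is left untouched.
#'
#' @param x_grid Uniform position grid, mm (0 = beam axis).
#' @param model A [lateral_profile_model()].
#' @return Dose values (a.u.) on `x_grid`.
#' @export
lateral_profile <- function(x_grid, model) {
  stopifnot(inherits(model, "lateral_profile_model"))
  if (length(x_grid) > 2 &&
      max(abs(diff(diff(x_grid)))) > 1e-9 * mean(abs(diff(x_grid))))
    stop("x_grid must be uniform")
  a <- model$field_radius
  s2 <- model$penumbra_sigma * sqrt(2)
  d <- 0.5 * (pracma::erf((x_grid + a) / s2) - pracma::erf((x_grid - a) / s2))
  d[x_grid > 0] <- d[x_grid > 0] * model$asymmetry_factor
  if (model$noise_sigma > 0) {
    noise <- .with_local_seed(model$seed,
                              stats::rnorm(length(d), 1, model$noise_sigma))
    d <- d * noise
  }
  d
}

# Run expr under a given seed, restoring the caller's RNG state afterwards.
.with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
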