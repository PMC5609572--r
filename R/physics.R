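# Range-energy tables are expensive enough to build once per material;
# cache keyed on the model's physical fields.
.range_cache <- new.env(parent = emptyenv())

.model_key <- function(model) {
  paste(model$material_name, model$density, model$mean_excitation_energy,
        model$Z_over_A, model$mode,
        if (!is.null(model$table)) nrow(model$table) else 0, sep = "|")
}

.bethe_mass_stopping <- function(E, Z_over_A, I_eV) {
  g <- 1 + E / .const$mp
  beta2 <- 1 - 1 / g^2
  b2g2 <- beta2 * g^2
  I <- I_eV * 1e-6
  Tmax <- 2 * .const$me * b2g2 /
    (1 + 2 * g * .const$me / .const$mp + (.const$me / .const$mp)^2)
  .const$K * Z_over_A / beta2 *
    (0.5 * log(2 * .const$me * b2g2 * Tmax / I^2) - beta2)
}

.check_energy_range <- function(E, lo = .const$E_MIN, hi = .const$E_MAX) {
  if (any(!is.finite(E)) || any(E < lo) || any(E > hi))
    stop(sprintf("energy outside the supported range [%g, %g] MeV", lo, hi))
}

#' Proton mass stopping power
#'
#' Unrestricted electronic stopping power of protons, from the Bethe formula
#' (no shell or density corrections) or by log-log interpolation of the
#' model's table. Vectorized over `E`.
#'
#' @param E Kinetic energy in MeV, within 0.1-300 MeV.
#' @param model A [stopping_power_model()].
#' @param units `"MeV.cm2.g"` (mass stopping power, default) or `"keV.um"`
#'   (linear stopping power through the model density).
#' @return Stopping power, same length as `E`.
#' @examples
#' stopping_power(62, water_model(), units = "keV.um")  # about 1 keV/um
#' @export
stopping_power <- function(E, model, units = c("MeV.cm2.g", "keV.um")) {
  units <- match.arg(units)
  stopifnot(inherits(model, "stopping_power_model"))
  .check_energy_range(E)
  S <- if (model$mode == "bethe") {
    .bethe_mass_stopping(E, model$Z_over_A, model$mean_excitation_energy)
  } else {
    tab <- model$table
    if (any(E < tab[1, 1]) || any(E > tab[nrow(tab), 1]))
      stop(sprintf("energy outside the tabulated range [%g, %g] MeV",
                   tab[1, 1], tab[nrow(tab), 1]))
    exp(stats::approx(log(tab[, 1]), log(tab[, 2]), xout = log(E))$y)
  }
  if (any(S <= 0))
    stop(sprintf("non-positive stopping power in %s at the requested energy",
                 model$material_name))
  if (units == "keV.um") S * model$density / 10 else S
}

# Cumulative-trapezoid range table on a log energy grid, from the lowest
# energy at which the Bethe bracket is safely positive (always E_MIN for the
# low-Z materials; higher for heavy metals, where sub-MeV protons are outside
# the model's validity anyway).
.range_table <- function(model, n = 4000L) {
  key <- .model_key(model)
  if (!is.null(.range_cache[[key]])) return(.range_cache[[key]])
  lo <- .const$E_MIN
  hi <- .const$E_MAX
  if (model$mode == "table") {
    lo <- max(lo, model$table[1, 1])
    hi <- min(hi, model$table[nrow(model$table), 1])
  } else {
    # walk up until the Bethe bracket is comfortably positive
    probe <- exp(seq(log(lo), log(5), length.out = 200))
    ok <- .bethe_mass_stopping(probe, model$Z_over_A, model$mean_excitation_energy) > 0.05
    if (!all(ok)) lo <- probe[max(which(!ok)) + 1L]
  }
  E <- exp(seq(log(lo), log(hi), length.out = n))
  S <- stopping_power(E, model)
  # R(E) = int dE'/S  (g/cm^2), integrated in log-energy: dE = E dlnE
  R <- pracma::cumtrapz(log(E), E / S)[, 1]
  # log-log monotone spline above the first grid cell; linear bridge from
  # (lo, 0) across the first cell, where R is vanishingly small anyway
  fwd <- stats::splinefun(log(E[-1]), log(R[-1]), method = "hyman")
  E2 <- E[2]; R2 <- R[2]
  tab <- list(E = E, R = R, lo = lo, hi = hi,
              R_of_E = function(e) {
                r <- numeric(length(e))
                hiidx <- e > E2
                r[hiidx] <- exp(fwd(log(e[hiidx])))
                loidx <- !hiidx & e > lo
                r[loidx] <- R2 * (e[loidx] - lo) / (E2 - lo)
                r
              })
  .range_cache[[key]] <- tab
  tab
}

#' CSDA range of a proton
#'
#' Continuous-slowing-down-approximation range, the integral of 1/S(E') from
#' the lower edge of the supported energy range up to `E`. The residual range
#' of protons below that edge (about 2 um of water) is neglected.
#'
#' @inheritParams stopping_power
#' @param units `"g.cm2"` (areal density, default) or `"mm"` (path length
#'   through the model density).
#' @return Range, same length as `E`; strictly increasing in `E`.
#' @examples
#' csda_range(62, water_model(), units = "mm")  # about 32 mm of water
#' @export
csda_range <- function(E, model, units = c("g.cm2", "mm")) {
  units <- match.arg(units)
  stopifnot(inherits(model, "stopping_power_model"))
  .check_energy_range(E)
  tab <- .range_table(model)
  R <- tab$R_of_E(E)
  if (units == "mm") R / model$density * 10 else R
}

#' Energy whose CSDA range equals a given residual range
#'
#' Inverse of [csda_range()], solved on the same range-energy relation so the
#' round trip is exact to the root-finder tolerance.
#'
#' @param R Residual range in g/cm^2 (or mm with `units = "mm"`).
#' @param model A [stopping_power_model()].
#' @param units Units of `R`.
#' @return Energy in MeV; 0 where `R` is at or below the range of the lowest
#'   supported energy.
#' @export
energy_at_residual_range <- function(R, model, units = c("g.cm2", "mm")) {
  units <- match.arg(units)
  stopifnot(inherits(model, "stopping_power_model"))
  if (units == "mm") R <- R * model$density / 10
  tab <- .range_table(model)
  Rmax <- tab$R[length(tab$R)]
  if (any(R > Rmax))
    stop(sprintf("residual range exceeds the range of a %g MeV proton", tab$hi))
  vapply(R, function(r) {
    if (r <= tab$R[1]) return(0)
    stats::uniroot(function(e) tab$R_of_E(e) - r,
                   lower = tab$lo, upper = tab$hi,
                   tol = 1e-12 * tab$hi)$root
  }, numeric(1))
}

#' A slab of material in the beam path
#'
#' @param material A [stopping_power_model()].
#' @param thickness_um Slab thickness in micrometres, >= 0.
#' @return An object of class `material_slab`.
#' @examples
#' material_slab(kapton_model(), 50)
#' @export
material_slab <- function(material, thickness_um) {
  stopifnot(inherits(material, "stopping_power_model"))
  if (!is.numeric(thickness_um) || length(thickness_um) != 1L || thickness_um < 0)
    stop("thickness_um must be a single non-negative number")
  structure(list(material = material, thickness_um = thickness_um),
            class = "material_slab")
}

#' @export
print.material_slab <- function(x, ...) {
  cat(sprintf("<material_slab> %g um %s\n", x$thickness_um,
              x$material$material_name))
  invisible(x)
}

#' Default passive-element stack of the beamline
#'
#' The thin absorbers a 62 MeV ocular beam crosses before the phantom: the
#' 50 um Kapton vacuum-exit window and the 15 um + 25 um tantalum scattering
#' foils of the double-foil system.
#'
#' @return List of [material_slab()] objects.
#' @export
beamline_slabs <- function() {
  list(material_slab(tantalum_model(), 15),
       material_slab(kapton_model(), 50),
       material_slab(tantalum_model(), 25))
}

#' Degrade a proton through a stack of slabs
#'
#' CSDA slowing through each slab in order: in each material the residual
#' range is reduced by the slab's areal thickness and mapped back to energy.
#'
#' @param E_in Incident kinetic energy, MeV.
#' @param slabs List of [material_slab()] objects (may be empty).
#' @return Residual energy in MeV after the full stack.
#' @examples
#' degrade_energy(62, beamline_slabs())  # loses well under 1 MeV
#' @export
degrade_energy <- function(E_in, slabs) {
  .check_energy_range(E_in)
  stopifnot(is.list(slabs))
  E <- E_in
  for (slab in slabs) {
    stopifnot(inherits(slab, "material_slab"))
    if (slab$thickness_um == 0) next
    t_gcm2 <- slab$thickness_um * 1e-4 * slab$material$density
    R <- csda_range(E, slab$material)
    if (R <= t_gcm2)
      stop(sprintf("proton stopped in %s (range %.4g g/cm^2 <= slab %.4g g/cm^2)",
                   slab$material$material_name, R, t_gcm2))
    E <- energy_at_residual_range(R - t_gcm2, slab$material)
  }
  E
}
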