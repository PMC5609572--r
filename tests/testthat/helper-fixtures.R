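# Shared fixtures, built in code.

water <- water_model()

# trapezoid depth-dose curve: linear ramp up over [plateau_lo - ramp, plateau_lo],
# flat plateau, linear ramp down over [plateau_hi, plateau_hi + ramp]
trapezoid_curve <- function(plateau_lo = 10, plateau_hi = 25, ramp = 2,
                            step = 0.05, height = 1) {
  z <- seq(plateau_lo - ramp - 2, plateau_hi + ramp + 2, by = step)
  d <- pmin(pmax((z - (plateau_lo - ramp)) / ramp, 0),
            pmax(pmin(((plateau_hi + ramp) - z) / ramp, 1), 0))
  cbind(z, height * pmin(d, 1))
}

# independent Bethe evaluation for oracle tests (deliberately re-derived,
# not shared with the package internals)
oracle_bethe_water <- function(E) {
  K <- 0.307075; me <- 0.51099895; mp <- 938.27208816
  ZA <- 0.55509; I <- 75e-6
  g <- 1 + E / mp
  b2 <- 1 - 1 / g^2
  b2g2 <- b2 * g^2
  Tmax <- 2 * me * b2g2 / (1 + 2 * g * me / mp + (me / mp)^2)
  K * ZA / b2 * (0.5 * log(2 * me * b2g2 * Tmax / I^2) - b2)
}

# small random fluence spectrum on a fixed RNG stream
random_spectrum <- function(n_depth = 3, n_species = 2, n_bins = 8,
                            rng = NULL) {
  edges <- sort(runif(n_bins + 1, 1, 200))
  sp <- data.frame(name = paste0("s", seq_len(n_species)),
                   charge = sample(1:2, n_species, replace = TRUE),
                   mass_number = 1)
  sp$mass_number <- ifelse(sp$charge == 2, 4, 1)
  counts <- array(runif(n_depth * n_species * n_bins),
                  dim = c(n_depth, n_species, n_bins))
  fluence_spectrum(seq_len(n_depth), sp, edges, counts)
}
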