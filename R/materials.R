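# Physical constants (MeV unless noted)
.const <- list(
  K      = 0.307075,     # 4 pi N_A r_e^2 m_e c^2, MeV cm^2 / mol
  me     = 0.51099895,   # electron rest energy
  mp     = 938.27208816, # proton rest energy
  E_MIN  = 0.1,          # lower edge of the supported proton energy range, MeV
  E_MAX  = 300           # upper edge, MeV
)

#' Stopping-power model for a material
#'
#' Describes how protons lose energy in a single homogeneous material, either
#' through the Bethe formula (mode `"bethe"`) or through log-log interpolation
#' of a user-supplied table of mass stopping powers (mode `"table"`).
#'
#' @param material_name Character label, e.g. `"water"`.
#' @param density Mass density in g/cm^3. Must be positive.
#' @param mean_excitation_energy Mean excitation energy I in eV. Must be
#'   positive. For liquid water the ICRU value 75 eV is used.
#' @param Z_over_A Ratio of atomic number to mass number (mol/g scale folded
#'   into the Bethe constant).
#' @param mode `"bethe"` for the closed-form Bethe evaluation, `"table"` for
#'   interpolation of `table`.
#' @param table Optional two-column matrix or data frame with energies (MeV,
#'   strictly increasing) and mass stopping powers (MeV cm^2/g). Required when
#'   `mode = "table"`.
#'
#' @return An object of class `stopping_power_model`.
#' @examples
#' w <- water_model()
#' stopping_power(62, w)
#' @export
stopping_power_model <- function(material_name, density, mean_excitation_energy,
                                 Z_over_A, mode = c("bethe", "table"),
                                 table = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.character(material_name), length(material_name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a single positive number (g/cm^3)")
  if (!is.numeric(mean_excitation_energy) || mean_excitation_energy <= 0)
    stop("mean_excitation_energy must be positive (eV)")
  if (!is.numeric(Z_over_A) || Z_over_A <= 0 || Z_over_A > 1)
    stop("Z_over_A must be in (0, 1]")
  if (mode == "table") {
    if (is.null(table)) stop("table mode requires a table of (MeV, MeV cm^2/g)")
    table <- as.matrix(table)
    if (ncol(table) != 2L) stop("stopping-power table must have two columns")
    if (any(diff(table[, 1]) <= 0)) stop("table energies must be strictly increasing")
    if (any(table[, 2] <= 0)) stop("table stopping powers must be positive")
  }
  structure(
    list(material_name = material_name, density = density,
         mean_excitation_energy = mean_excitation_energy,
         Z_over_A = Z_over_A, mode = mode, table = table),
    class = "stopping_power_model")
}

#' @export
print.stopping_power_model <- function(x, ...) {
  cat(sprintf("<stopping_power_model> %s  rho = %g g/cm^3  I = %g eV  Z/A = %g  mode = %s\n",
              x$material_name, x$density, x$mean_excitation_energy,
              x$Z_over_A, x$mode))
  invisible(x)
}

#' Built-in material models
#'
#' Convenience constructors for the materials a passive ocular proton beamline
#' is made of: the water phantom, the Kapton vacuum-exit window, the tantalum
#' scattering foils, dry air and PMMA (modulator / range-shifter plastic).
#' Densities, Z/A and mean excitation energies are the ICRU/NIST reference
#' values.
#'
#' @return A `stopping_power_model`.
#' @export
water_model <- function() {
  stopping_power_model("water", 1.0, 75, 0.55509, "bethe")
}

#' @rdname water_model
#' @export
kapton_model <- function() {
  stopping_power_model("kapton", 1.42, 79.6, 0.51264, "bethe")
}

#' @rdname water_model
#' @export
tantalum_model <- function() {
  stopping_power_model("tantalum", 16.654, 718, 0.40343, "bethe")
}

#' @rdname water_model
#' @export
air_model <- function() {
  stopping_power_model("air", 1.20479e-3, 85.7, 0.49919, "bethe")
}

#' @rdname water_model
#' @export
pmma_model <- function() {
  stopping_power_model("pmma", 1.19, 74, 0.53937, "bethe")
}

#' Read / write a stopping-power table file
#'
#' Two-column whitespace-separated text (energy MeV, mass stopping power
#' MeV cm^2/g) with `#` comment headers carrying `name:`, `density:` (g/cm^3)
#' and `I:` (eV) metadata. The reader returns a table-mode
#' [stopping_power_model()].
#'
#' @param path File path.
#' @param model A `stopping_power_model` (write) .
#' @param energies Energies (MeV) at which the table is evaluated when writing
#'   from a bethe-mode model; defaults to 500 log-spaced points over the
#'   supported range.
#' @return `read_stopping_table` returns a `stopping_power_model` in table
#'   mode; `write_stopping_table` returns `path` invisibly.
#' @export
read_stopping_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  get_meta <- function(key, default = NA_character_) {
    hit <- grep(paste0(key, ":"), hdr, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(paste0(".*", key, ":\\s*"), "", hit[1]))
  }
  name <- get_meta("name", "table-material")
  density <- suppressWarnings(as.numeric(get_meta("density", "1")))
  I <- suppressWarnings(as.numeric(get_meta("I", "75")))
  ZA <- suppressWarnings(as.numeric(get_meta("Z_over_A", "0.5")))
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- lapply(strsplit(trimws(body), "\\s+"),
                   function(f) suppressWarnings(as.numeric(f)))
  bad <- which(vapply(fields, function(f) length(f) != 2L || anyNA(f), logical(1)))
  if (length(bad))
    stop(sprintf("malformed stopping-table row at line %d of %s",
                 which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))[bad[1]], path))
  tab <- do.call(rbind, fields)
  stopping_power_model(name, density, I, ZA, mode = "table", table = tab)
}

#' @rdname read_stopping_table
#' @export
write_stopping_table <- function(model, path, energies = NULL) {
  stopifnot(inherits(model, "stopping_power_model"))
  if (is.null(energies))
    energies <- exp(seq(log(.const$E_MIN), log(.const$E_MAX), length.out = 500))
  S <- stopping_power(energies, model)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# name: %s", model$material_name),
    sprintf("# density: %.6g", model$density),
    sprintf("# I: %.6g", model$mean_excitation_energy),
    sprintf("# Z_over_A: %.6g", model$Z_over_A),
    "# columns: energy_MeV mass_stopping_power_MeV_cm2_g"), con)
  writeLines(sprintf("%.17g %.17g", energies, S), con)
  invisible(path)
}
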