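#' Ionization-chamber calibration data
#'
#' Calibration of a reference chamber in terms of absorbed dose to water at
#' a reference quality (typically Co-60): the calibration factor `N_DwQ0`
#' and a table of beam-quality correction factors `kQ` versus residual range
#' `Rres` (the proton beam-quality index).
#'
#' @param chamber_name Character label.
#' @param N_DwQ0 Calibration factor, Gy per reading unit; positive.
#' @param kQ_table Two-column matrix or data frame (Rres mm strictly
#'   increasing, kQ in `[0.9, 1.1]`).
#' @param reference_quality Label of the reference quality (default "Co-60").
#' @return Object of class `chamber_calibration`.
#' @export
chamber_calibration <- function(chamber_name, N_DwQ0, kQ_table,
                                reference_quality = "Co-60") {
  if (!is.numeric(N_DwQ0) || N_DwQ0 <= 0) stop("N_DwQ0 must be positive")
  kQ_table <- as.matrix(kQ_table)
  if (ncol(kQ_table) != 2L) stop("kQ_table must have columns (Rres mm, kQ)")
  if (nrow(kQ_table) >= 2 && any(diff(kQ_table[, 1]) <= 0))
    stop("kQ_table Rres values must be strictly increasing")
  if (any(kQ_table[, 2] < 0.9 | kQ_table[, 2] > 1.1))
    stop("kQ values outside the plausible [0.9, 1.1] band")
  structure(list(chamber_name = chamber_name, N_DwQ0 = N_DwQ0,
                 kQ_table = kQ_table, reference_quality = reference_quality),
            class = "chamber_calibration")
}

#' @export
print.chamber_calibration <- function(x, ...) {
  cat(sprintf("<chamber_calibration> %s  N_D,w,Q0 = %g Gy/rdg  (ref %s, %d kQ points)\n",
              x$chamber_name, x$N_DwQ0, x$reference_quality, nrow(x$kQ_table)))
  invisible(x)
}

#' Influence-corrected chamber reading
#'
#' @param M_Q Raw reading, positive.
#' @param influence_corrections Optional named numeric vector of
#'   multiplicative correction factors (temperature-pressure, polarity,
#'   recombination, ...), applied to `M_Q`.
#' @return Object of class `chamber_reading`.
#' @export
chamber_reading <- function(M_Q, influence_corrections = numeric(0)) {
  if (!is.numeric(M_Q) || length(M_Q) != 1L || M_Q <= 0)
    stop("M_Q must be a single positive reading")
  if (length(influence_corrections) &&
      (is.null(names(influence_corrections)) || any(!nzchar(names(influence_corrections)))))
    stop("influence corrections must be labeled (named)")
  structure(list(M_Q = M_Q, influence_corrections = influence_corrections),
            class = "chamber_reading")
}

#' Absorbed dose to water from a chamber reading
#'
#' `D_w,Q = M_Q * N_D,w,Q0 * kQ(Rres)`: the influence-corrected reading times
#' the absorbed-dose calibration factor times the chamber-specific
#' beam-quality factor, with `kQ` linearly interpolated on the residual
#' range. Residual ranges outside the tabulated span are refused rather
#' than extrapolated.
#'
#' @param reading A [chamber_reading()] (or a bare positive number).
#' @param cal A [chamber_calibration()].
#' @param Rres Residual range of the user beam, mm.
#' @return Absorbed dose in Gy.
#' @examples
#' cal <- chamber_calibration("markus", 0.5,
#'                            cbind(c(10, 20), c(1.00, 1.01)))
#' absorbed_dose(chamber_reading(10), cal, Rres = 15)
#' @export
absorbed_dose <- function(reading, cal, Rres) {
  if (is.numeric(reading)) reading <- chamber_reading(reading)
  stopifnot(inherits(reading, "chamber_reading"),
            inherits(cal, "chamber_calibration"))
  tab <- cal$kQ_table
  if (Rres < tab[1, 1] || Rres > tab[nrow(tab), 1])
    stop(sprintf("Rres = %g mm outside the kQ table span [%g, %g] mm; refusing to extrapolate",
                 Rres, tab[1, 1], tab[nrow(tab), 1]))
  kQ <- if (nrow(tab) == 1L) tab[1, 2] else
    stats::approx(tab[, 1], tab[, 2], xout = Rres)$y
  M <- reading$M_Q * prod(reading$influence_corrections)
  M * cal$N_DwQ0 * kQ
}

#' Monitor-unit calibration of the transmission chambers
#'
#' Converts a dose measured at the mid-SOBP reference depth and the monitor
#' units counted during the measurement into the monitor calibration in
#' cGy per MU.
#'
#' @param D Dose in Gy.
#' @param monitor_units Monitor units counted; positive.
#' @return Calibration in cGy/MU.
#' @examples
#' monitor_calibration(1, 100)  # 1 cGy/MU
#' @export
monitor_calibration <- function(D, monitor_units) {
  if (!is.numeric(monitor_units) || monitor_units <= 0)
    stop("monitor_units must be positive")
  if (D < 0) stop("dose must be non-negative")
  100 * D / monitor_units
}

#' Normalize output factors to the reference collimator
#'
#' Output factors (dose per monitor unit) of a set of collimators are
#' divided by the reference-collimator entry; entries whose normalized
#' output drops below `1 - drop_bound` are flagged (the field-size
#' dependence of a well-commissioned passive line stays within a few
#' percent down to the smallest clinical collimator).
#'
#' @param entries Two-column matrix or data frame (collimator area mm²,
#'   raw output factor).
#' @param reference_area Area of the reference collimator, mm² (default 490,
#'   the 25 mm diameter circular collimator).
#' @param drop_bound Allowed relative drop before flagging (default 0.03).
#' @return Object of class `output_factor_set`: data frame with `area_mm2`,
#'   `OF` (reference entry exactly 1) and logical `flagged`.
#' @export
normalize_output_factors <- function(entries, reference_area = 490,
                                     drop_bound = 0.03) {
  m <- as.matrix(entries)
  if (ncol(m) != 2L) stop("entries must be (area mm^2, output factor) pairs")
  if (any(m[, 2] <= 0)) stop("output factors must be positive")
  ref <- which(m[, 1] == reference_area)
  if (!length(ref))
    stop(sprintf("no entry at the reference area %g mm^2", reference_area))
  OF <- m[, 2] / m[ref[1], 2]
  structure(
    list(entries = data.frame(area_mm2 = m[, 1], OF = OF,
                              flagged = OF < 1 - drop_bound),
         reference_area = reference_area, drop_bound = drop_bound),
    class = "output_factor_set")
}

#' @export
print.output_factor_set <- function(x, ...) {
  cat(sprintf("<output_factor_set> reference %g mm^2, drop bound %g%%\n",
              x$reference_area, 100 * x$drop_bound))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Average dose rate of a pulsed beam
#'
#' Bookkeeping for pulsed (e.g. laser-driven) beams: dose per pulse times
#' repetition rate, expressed per minute.
#'
#' @param dose_per_pulse Dose per pulse, Gy; non-negative.
#' @param repetition_rate Pulse repetition rate, Hz; non-negative.
#' @return Average dose rate in Gy/min.
#' @examples
#' average_dose_rate(0.02, 1)  # 1.2 Gy/min
#' @export
average_dose_rate <- function(dose_per_pulse, repetition_rate) {
  if (any(dose_per_pulse < 0) || any(repetition_rate < 0))
    stop("dose per pulse and repetition rate must be non-negative")
  dose_per_pulse * repetition_rate * 60
}

#' Read / write a chamber calibration file
#'
#' Text format: `#` comments, header lines `name: <label>` and
#' `N_DwQ0: <Gy per reading>`, then two-column `Rres_mm kQ` body.
#'
#' @param path File path.
#' @param cal A [chamber_calibration()] (write only).
#' @return `read_chamber_calibration` returns a `chamber_calibration`;
#'   the writer returns `path` invisibly.
#' @export
read_chamber_calibration <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- trimws(lines[keep])
  name_i <- grep("^name:", body)
  n_i <- grep("^N_DwQ0:", body)
  if (!length(name_i) || !length(n_i))
    stop("calibration file needs 'name:' and 'N_DwQ0:' header lines")
  name <- trimws(sub("^name:", "", body[name_i[1]]))
  N <- as.numeric(trimws(sub("^N_DwQ0:", "", body[n_i[1]])))
  rows <- body[-c(name_i, n_i)]
  m <- do.call(rbind, lapply(strsplit(rows, "\\s+"), as.numeric))
  chamber_calibration(name, N, m)
}

#' @rdname read_chamber_calibration
#' @export
write_chamber_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "chamber_calibration"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# chamber calibration: Rres_mm kQ",
               paste0("name: ", cal$chamber_name),
               sprintf("N_DwQ0: %.17g", cal$N_DwQ0),
               sprintf("%.17g %.17g", cal$kQ_table[, 1], cal$kQ_table[, 2])),
             con)
  invisible(path)
}
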