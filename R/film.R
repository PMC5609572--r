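#' Radiochromic film scan
#'
#' A digitized film in transmission mode: 16-bit red-channel intensities,
#' the scan resolution, and the intensity of unexposed film (the netOD
#' reference, which folds in the film base).
#'
#' @param pixel_matrix Integer-valued matrix of intensities in `[1, 65535]`.
#' @param dpi Scan resolution, dots per inch; positive.
#' @param background_value Unexposed-film intensity, in `[1, 65535]`.
#' @return Object of class `film_scan`.
#' @export
film_scan <- function(pixel_matrix, dpi, background_value) {
  pixel_matrix <- as.matrix(pixel_matrix)
  if (any(pixel_matrix < 1 | pixel_matrix > 65535))
    stop("pixel intensities must lie in [1, 65535]")
  if (!is.numeric(dpi) || dpi <= 0) stop("dpi must be positive")
  if (background_value < 1 || background_value > 65535)
    stop("background_value must lie in [1, 65535]")
  structure(list(pixel_matrix = pixel_matrix, dpi = dpi,
                 background_value = background_value),
            class = "film_scan")
}

#' @export
print.film_scan <- function(x, ...) {
  cat(sprintf("<film_scan> %d x %d px at %g dpi (%.3f mm/px), background %g\n",
              nrow(x$pixel_matrix), ncol(x$pixel_matrix), x$dpi,
              25.4 / x$dpi, x$background_value))
  invisible(x)
}

#' Net optical density
#'
#' `netOD = log10(I_unexposed / I_exposed)`, element-wise; non-negative when
#' the exposed intensity does not exceed the unexposed one. Invariant under
#' a common rescale of both intensities.
#'
#' @param exposed_intensity Exposed-film intensity (scalar, vector or matrix).
#' @param unexposed_intensity Unexposed-film intensity, positive.
#' @return netOD, same shape as `exposed_intensity`.
#' @examples
#' net_od(4000, 40000)  # 1
#' @export
net_od <- function(exposed_intensity, unexposed_intensity) {
  if (any(exposed_intensity <= 0) || any(unexposed_intensity <= 0))
    stop("intensities must be positive")
  log10(unexposed_intensity / exposed_intensity)
}

#' Fit a third-order netOD-to-dose calibration
#'
#' Least-squares cubic mapping netOD directly to dose so that converting a
#' film is polynomial evaluation, not root finding. The fitted curve must be
#' strictly increasing over the span of the calibration points.
#'
#' @param net_ods netOD values of the calibration strips.
#' @param doses Delivered doses in Gy, same length; the standard protocol
#'   spans 0.25-4 Gy.
#' @param constrain_origin Force dose(netOD = 0) = 0 (default TRUE).
#' @param valid_dose_range Dose validity interval in Gy stored with the
#'   curve (default `c(0.25, 4)`).
#' @return Object of class `calibration_curve` with `coefficients` (constant
#'   through cubic term), `fit_residual_rms` (Gy), `netod_span` and
#'   `valid_dose_range`.
#' @export
fit_calibration <- function(net_ods, doses, constrain_origin = TRUE,
                            valid_dose_range = c(0.25, 4)) {
  if (length(net_ods) != length(doses)) stop("net_ods and doses differ in length")
  if (length(net_ods) < 5) stop("need at least 5 calibration points")
  X <- cbind(net_ods, net_ods^2, net_ods^3)
  if (!constrain_origin) X <- cbind(1, X)
  fit <- stats::lm.fit(X, doses)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  coefs <- if (constrain_origin) c(0, cf) else cf
  names(coefs) <- c("c0", "c1", "c2", "c3")
  span <- range(net_ods)
  grid <- seq(span[1], span[2], length.out = 512)
  slope <- coefs[2] + 2 * coefs[3] * grid + 3 * coefs[4] * grid^2
  if (any(slope <= 0))
    stop("fitted calibration is not strictly increasing over the data span; add points or lower the order")
  structure(list(coefficients = coefs,
                 fit_residual_rms = sqrt(mean(fit$residuals^2)),
                 netod_span = span, valid_dose_range = valid_dose_range,
                 constrain_origin = constrain_origin),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> dose = %.4g + %.4g x + %.4g x^2 + %.4g x^3 (x = netOD)\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$coefficients[4]))
  cat(sprintf("  residual RMS %.4g Gy, valid %.3g-%.3g Gy\n",
              x$fit_residual_rms, x$valid_dose_range[1], x$valid_dose_range[2]))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' @param curve A [fit_calibration()] result.
#' @param netod netOD values (any shape).
#' @return Dose in Gy, same shape.
#' @export
calibration_dose <- function(curve, netod) {
  stopifnot(inherits(curve, "calibration_curve"))
  cf <- unname(curve$coefficients)
  cf[1] + cf[2] * netod + cf[3] * netod^2 + cf[4] * netod^3
}

#' Invert a calibration curve
#'
#' Solves dose(netOD) = D for netOD on the monotone cubic: a vectorized
#' interpolation seed refined by Newton iterations to machine precision.
#' Used by the synthetic film generator.
#'
#' @param curve A `calibration_curve`.
#' @param dose Dose values in Gy (any shape); doses at or below dose(0)
#'   map to netOD 0.
#' @return netOD values, same shape.
#' @export
calibration_netod <- function(curve, dose) {
  stopifnot(inherits(curve, "calibration_curve"))
  cf <- unname(curve$coefficients)
  hi <- max(curve$netod_span[2], 2)
  while (calibration_dose(curve, hi) < max(dose)) hi <- 2 * hi
  grid <- seq(0, hi, length.out = 2048)
  x <- stats::approx(calibration_dose(curve, grid), grid,
                     xout = pmax(dose, cf[1]))$y
  for (i in 1:4) {  # Newton polish on the monotone cubic
    f <- calibration_dose(curve, x) - dose
    fp <- cf[2] + 2 * cf[3] * x + 3 * cf[4] * x^2
    x <- x - f / fp
  }
  x <- pmax(x, 0)
  x[dose <= cf[1]] <- 0
  if (is.matrix(dose)) x <- matrix(x, nrow(dose), ncol(dose))
  x
}

#' Convert a film scan into a 2D dose map
#'
#' Per-pixel netOD against the unexposed background, evaluated through the
#' calibration cubic. Pixel coordinates are centred on the scan, with a
#' pitch of `25.4 / dpi` mm. Doses above the calibration validity range are
#' flagged, never clipped; a warning is raised when more than 1% of the
#' in-field pixels (dose above 10% of the map maximum) are out of range.
#'
#' @param scan A [film_scan()].
#' @param curve A `calibration_curve`.
#' @return Object of class `dose_map`: `dose` (Gy matrix), `x_mm` (columns),
#'   `y_mm` (rows), `pixel_pitch` (mm), logical `out_of_range` matrix.
#' @export
dose_map <- function(scan, curve) {
  stopifnot(inherits(scan, "film_scan"), inherits(curve, "calibration_curve"))
  nod <- net_od(scan$pixel_matrix, scan$background_value)
  nod[nod < 0] <- 0   # scanner noise can push unexposed pixels above background
  dose <- calibration_dose(curve, nod)
  oor <- dose > curve$valid_dose_range[2]
  infield <- dose > 0.1 * max(dose)
  n_bad <- sum(oor & infield)
  if (sum(infield) > 0 && n_bad > 0.01 * sum(infield))
    warning(sprintf("%d in-field pixels above the calibrated dose range", n_bad))
  pitch <- 25.4 / scan$dpi
  nr <- nrow(dose); nc <- ncol(dose)
  structure(list(dose = dose,
                 x_mm = (seq_len(nc) - (nc + 1) / 2) * pitch,
                 y_mm = (seq_len(nr) - (nr + 1) / 2) * pitch,
                 pixel_pitch = pitch, out_of_range = oor),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d px, pitch %.3f mm, max %.3g Gy, %d px out of range\n",
              nrow(x$dose), ncol(x$dose), x$pixel_pitch, max(x$dose),
              sum(x$out_of_range)))
  invisible(x)
}

#' Extract a central profile from a dose map
#'
#' @param map A [dose_map()].
#' @param axis `"x"` (central row, default) or `"y"` (central column).
#' @return Two-column matrix (position mm, dose Gy).
#' @export
dose_profile <- function(map, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(inherits(map, "dose_map"))
  if (axis == "x") {
    row <- which.min(abs(map$y_mm))
    cbind(position_mm = map$x_mm, dose_Gy = map$dose[row, ])
  } else {
    col <- which.min(abs(map$x_mm))
    cbind(position_mm = map$y_mm, dose_Gy = map$dose[, col])
  }
}

#' Simulate a film exposure
#'
#' Forward model for tests and examples: converts a dose distribution into
#' 16-bit film intensities through the inverse calibration, adds seeded
#' Gaussian digitization noise (default 0.2% of intensity) and quantizes to
#' integers. Labelled synthetic: no scanner or film-batch effects beyond
#' this noise are modelled.
#'
#' @param dose Matrix of doses in Gy.
#' @param curve A `calibration_curve`.
#' @param dpi Scan resolution (default 300).
#' @param background_value Unexposed intensity (default 40000).
#' @param noise_sigma Relative intensity noise (default 0.002; 0 disables).
#' @param seed Integer seed for the noise.
#' @return A [film_scan()].
#' @export
synthetic_film_scan <- function(dose, curve, dpi = 300,
                                background_value = 40000, noise_sigma = 0.002,
                                seed = 1L) {
  dose <- as.matrix(dose)
  nod <- calibration_netod(curve, dose)
  inten <- background_value * 10^(-nod)
  if (noise_sigma > 0) {
    fac <- .with_local_seed(seed, stats::rnorm(length(inten), 1, noise_sigma))
    inten <- inten * fac
  }
  px <- matrix(pmin(pmax(round(inten), 1), 65535), nrow(dose), ncol(dose))
  film_scan(px, dpi, background_value)
}

#' Read / write film matrices
#'
#' Plain-text film format: `#` header with `dpi:` and `background:`, then
#' one row of integer intensities per line. `read_film_tiff` reads a 16-bit
#' TIFF instead (red channel of RGB scans), and needs the `tiff` package.
#'
#' @param scan A [film_scan()] (write only).
#' @param path File path.
#' @param dpi,background_value Metadata for TIFF input, which carries neither.
#' @return Readers return a `film_scan`; the writer returns `path` invisibly.
#' @export
write_film_matrix <- function(scan, path) {
  stopifnot(inherits(scan, "film_scan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# film intensity matrix (16-bit red channel)",
               sprintf("# dpi: %.10g", scan$dpi),
               sprintf("# background: %.10g", scan$background_value),
               apply(scan$pixel_matrix, 1, paste, collapse = " ")), con)
  invisible(path)
}

#' @rdname write_film_matrix
#' @export
read_film_matrix <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  meta <- function(key, default) {
    hit <- grep(paste0(key, ":"), hdr, value = TRUE)
    if (!length(hit)) return(default)
    as.numeric(trimws(sub(paste0(".*", key, ":\\s*"), "", hit[1])))
  }
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  px <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  film_scan(px, meta("dpi", 300), meta("background", 40000))
}

#' @rdname write_film_matrix
#' @export
read_film_tiff <- function(path, dpi = 300, background_value = 40000) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF scans requires the 'tiff' package")
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]   # red channel
  film_scan(pmin(pmax(round(img * 65535), 1), 65535), dpi, background_value)
}

#' @rdname write_film_matrix
#' @export
write_film_tiff <- function(scan, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("writing TIFF scans requires the 'tiff' package")
  stopifnot(inherits(scan, "film_scan"))
  tiff::writeTIFF(scan$pixel_matrix / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
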