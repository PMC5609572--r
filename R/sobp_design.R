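#' Modulator-wheel specification
#'
#' An ordered list of modulator steps. Each step is a (water-equivalent
#' thickness, weight) pair; a step of thickness zero represents the air gap
#' (the unmodulated, deepest component) and is only allowed in first
#' position. In relative mode the weights sum to one; weights summing to
#' something else are renormalized with a warning.
#'
#' @param thickness Step thicknesses in mm water-equivalent, >= 0.
#' @param weight Step weights, >= 0, same length as `thickness`.
#' @param weight_mode `"relative"` (weights sum to 1) or `"absolute"`.
#' @return Object of class `modulator_spec` with a `steps` data frame.
#' @examples
#' modulator_spec(c(0, 0.8, 1.6), c(0.7, 0.2, 0.1))
#' @export
modulator_spec <- function(thickness, weight,
                           weight_mode = c("relative", "absolute")) {
  weight_mode <- match.arg(weight_mode)
  if (length(thickness) < 1L || length(thickness) != length(weight))
    stop("need at least one step, with one weight per thickness")
  if (any(thickness < 0)) stop("step thicknesses must be non-negative")
  if (any(thickness[-1] == 0))
    stop("only the first step may have zero thickness (the air gap)")
  if (any(weight < 0)) stop("step weights must be non-negative")
  if (weight_mode == "relative") {
    s <- sum(weight)
    if (s <= 0) stop("relative weights must have a positive sum")
    if (abs(s - 1) > 1e-9) {
      warning(sprintf("relative weights sum to %.6g; renormalizing to 1", s))
      weight <- weight / s
    }
  }
  structure(list(steps = data.frame(thickness = thickness, weight = weight),
                 weight_mode = weight_mode),
            class = "modulator_spec")
}

#' @export
print.modulator_spec <- function(x, ...) {
  cat(sprintf("<modulator_spec> %d steps, %s weights%s\n", nrow(x$steps),
              x$weight_mode,
              if (x$steps$thickness[1] == 0) " (first step = air gap)" else ""))
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Read / write a modulator step file
#'
#' Plain-text dialect: `#` comment lines, one header line `mode: absolute`
#' or `mode: relative`, then one `thickness_mm weight` pair per line (zero
#' thickness = air gap). Writing uses full double precision so a read/write
#' round trip is bit-exact.
#'
#' @param path File path.
#' @param spec A [modulator_spec()] (write only).
#' @return `read_modulator` returns a `modulator_spec`; `write_modulator`
#'   returns `path` invisibly.
#' @export
read_modulator <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- trimws(lines[keep])
  lineno <- which(keep)
  mode_i <- grep("^mode:", body)
  if (!length(mode_i)) stop("modulator file is missing the 'mode:' header line")
  mode <- trimws(sub("^mode:", "", body[mode_i[1]]))
  if (!mode %in% c("absolute", "relative"))
    stop(sprintf("line %d: mode must be 'absolute' or 'relative', got '%s'",
                 lineno[mode_i[1]], mode))
  rows <- body[-mode_i]
  rowno <- lineno[-mode_i]
  if (!length(rows)) stop("modulator file has no step lines")
  parsed <- lapply(strsplit(rows, "\\s+"), function(f) suppressWarnings(as.numeric(f)))
  bad <- which(vapply(parsed, function(p) length(p) != 2L || anyNA(p), logical(1)))
  if (length(bad))
    stop(sprintf("line %d: expected 'thickness_mm weight'", rowno[bad[1]]))
  m <- do.call(rbind, parsed)
  if (any(m[, 1] < 0))
    stop(sprintf("line %d: negative step thickness", rowno[which(m[, 1] < 0)[1]]))
  if (any(m[, 2] < 0))
    stop(sprintf("line %d: negative step weight", rowno[which(m[, 2] < 0)[1]]))
  modulator_spec(m[, 1], m[, 2], weight_mode = mode)
}

#' @rdname read_modulator
#' @export
write_modulator <- function(spec, path) {
  stopifnot(inherits(spec, "modulator_spec"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# modulator step file: thickness_mm weight (zero thickness = air gap)",
               paste0("mode: ", spec$weight_mode),
               sprintf("%.17g %.17g", spec$steps$thickness, spec$steps$weight)),
             con)
  invisible(path)
}

#' Family of range-shifted pristine peaks for modulator design
#'
#' Generates the constituent peaks of an SOBP on one common depth grid: the
#' unshifted (air-gap) peak plus `n_steps - 1` peaks pulled back by
#' successive multiples of the step thickness. The step thickness defaults
#' to 80% of the pristine-peak FWHM, or to
#' `modulation_width / (n_steps - 1)` when a modulation width is requested.
#'
#' @inheritParams pristine_bragg
#' @param n_steps Number of steps including the air gap.
#' @param modulation_width Optional total pull-back span in mm.
#' @param step_mm Optional explicit step thickness in mm (overrides both
#'   defaults).
#' @return List of `pristine_peak` objects; each carries its shifter
#'   thickness in attribute `"shift"`.
#' @export
sobp_peak_family <- function(E = 62, n_steps = 10, modulation_width = NULL,
                             step_mm = NULL, grid_step = 0.1,
                             straggling_factor = 0.012) {
  if (n_steps < 1) stop("need at least one step")
  base <- pristine_bragg(E, grid_step, straggling_factor)
  if (is.null(step_mm)) {
    step_mm <- if (!is.null(modulation_width)) {
      if (n_steps < 2) stop("a modulation width needs at least two steps")
      modulation_width / (n_steps - 1)
    } else 0.8 * peak_fwhm(base)
  }
  grid_max <- max(base$depth_grid)
  shifts <- (seq_len(n_steps) - 1) * step_mm
  lapply(shifts, function(t) {
    pk <- apply_range_shifter(E, t, grid_step, straggling_factor,
                              grid_max = grid_max)
    attr(pk, "shift") <- t
    pk
  })
}

#' Full width at half maximum of a peaked curve
#'
#' @param peak A `pristine_peak` (or any depth-dose curve with a single peak).
#' @return FWHM in mm.
#' @export
peak_fwhm <- function(peak) {
  dd <- .as_depth_dose(peak)
  half <- max(dd$d) / 2
  .distal_crossing(dd$z, dd$d, half) - .proximal_crossing(dd$z, dd$d, half)
}

#' Superpose range-shifted peaks into an SOBP
#'
#' `dose(z) = sum_k w_k * peak_k(z)`, linear in the weights. One peak per
#' modulator step, all on a common depth grid.
#'
#' @param peaks List of `pristine_peak` objects on one common grid.
#' @param spec A [modulator_spec()] with one step per peak.
#' @return Object of class `sobp_curve` with `depth_grid`, `dose`,
#'   `component_weights` and `flat_region` (taken from `spec` when the spec
#'   was produced by [design_weights()], otherwise `NA`).
#' @export
synthesize_sobp <- function(peaks, spec) {
  stopifnot(inherits(spec, "modulator_spec"), is.list(peaks))
  w <- spec$steps$weight
  if (length(peaks) != length(w))
    stop(sprintf("%d peaks for %d modulator steps", length(peaks), length(w)))
  z <- peaks[[1]]$depth_grid
  for (k in seq_along(peaks)) {
    zk <- peaks[[k]]$depth_grid
    if (length(zk) != length(z) || max(abs(zk - z)) > 1e-9)
      stop(sprintf("peak %d is not on the common depth grid", k))
  }
  dose <- Reduce(`+`, Map(function(pk, wk) wk * pk$dose, peaks, w))
  structure(list(depth_grid = z, dose = dose, component_weights = w,
                 flat_region = attr(spec, "flat_region") %||% c(NA_real_, NA_real_)),
            class = "sobp_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sobp_curve <- function(x, ...) {
  cat(sprintf("<sobp_curve> %d components, %d depth points",
              length(x$component_weights), length(x$depth_grid)))
  if (!anyNA(x$flat_region))
    cat(sprintf(", flat region [%.2f, %.2f] mm", x$flat_region[1], x$flat_region[2]))
  cat("\n")
  invisible(x)
}

# Lawson-Hanson active-set non-negative least squares: min ||Ax - b|| s.t. x >= 0.
.nnls <- function(A, b, tol = NULL) {
  n <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * max(dim(A))
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive) && max(w[!passive]) > tol && iter < 30L * n) {
    iter <- iter + 1L
    cand <- which(!passive)
    passive[cand[which.max(w[cand])]] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      s[is.na(s)] <- 0
      if (all(s[passive] > tol)) break
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    x <- s
    w <- drop(crossprod(A, b - A %*% x))
  }
  pmax(x, 0)
}

#' Optimize modulator weights for a flat SOBP
#'
#' Finds non-negative step weights minimizing the squared deviation of the
#' superposed dose from a flat unit dose over the requested region
#' (non-negative least squares, Lawson-Hanson active set). Weights are
#' returned in relative mode; the achieved homogeneity
#' `(Dmax - Dmin)/(Dmax + Dmin) * 100` over the flat region is stored in
#' attribute `"achieved_homogeneity"`.
#'
#' @param peaks List of `pristine_peak` objects on one common grid (one per
#'   modulator step, as from [sobp_peak_family()]).
#' @param flat_proximal,flat_distal Flat-region bounds in mm; must lie inside
#'   the deepest peak's range.
#' @param tolerance Acceptable homogeneity as a fraction (default 0.02); if
#'   the optimum is worse, an error reports the achieved value.
#' @return A [modulator_spec()] (relative mode) with attributes
#'   `"achieved_homogeneity"` (percent) and `"flat_region"`.
#' @export
design_weights <- function(peaks, flat_proximal, flat_distal,
                           tolerance = 0.02) {
  stopifnot(is.list(peaks), length(peaks) >= 1)
  if (flat_proximal >= flat_distal)
    stop("flat_proximal must lie shallower than flat_distal")
  z <- peaks[[1]]$depth_grid
  deepest <- which.max(vapply(peaks, function(p) p$range90, numeric(1)))
  if (flat_distal > peaks[[deepest]]$range90)
    stop("flat region extends beyond the deepest peak's range")
  rows <- which(z >= flat_proximal & z <= flat_distal)
  if (length(rows) < length(peaks))
    stop("flat region too narrow for the number of steps")
  A <- vapply(peaks, function(p) p$dose[rows], numeric(length(rows)))
  w <- .nnls(A, rep(1, length(rows)))
  if (sum(w) <= 0) stop("optimizer returned all-zero weights")
  dose <- drop(A %*% w)
  hom <- (max(dose) - min(dose)) / (max(dose) + min(dose))
  if (hom > tolerance)
    stop(sprintf(
      "flatness infeasible with %d steps: achieved homogeneity %.2f%% > %.2f%%",
      length(peaks), 100 * hom, 100 * tolerance))
  thick <- vapply(seq_along(peaks), function(k) {
    s <- attr(peaks[[k]], "shift")
    if (!is.null(s)) s else peaks[[deepest]]$range90 - peaks[[k]]$range90
  }, numeric(1))
  spec <- modulator_spec(thick, w / sum(w), weight_mode = "relative")
  attr(spec, "achieved_homogeneity") <- 100 * hom
  attr(spec, "flat_region") <- c(flat_proximal, flat_distal)
  spec
}
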