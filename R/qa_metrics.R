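# --- crossing utilities ----------------------------------------------------

# All depths where the piecewise-linear curve (z, d) crosses `level`.
.crossings <- function(z, d, level) {
  n <- length(z)
  out <- numeric(0)
  eq <- which(d == level)
  if (length(eq)) out <- z[eq]
  i <- which((d[-n] - level) * (d[-1] - level) < 0)
  if (length(i))
    out <- c(out, z[i] + (level - d[i]) / (d[i + 1] - d[i]) * (z[i + 1] - z[i]))
  sort(unique(out))
}

.proximal_crossing <- function(z, d, level) {
  x <- .crossings(z, d, level)
  if (!length(x)) return(NA_real_)
  x[1]
}

.distal_crossing <- function(z, d, level) {
  x <- .crossings(z, d, level)
  if (!length(x)) return(NA_real_)
  x[length(x)]
}

# Accept a pristine_peak / sobp_curve, a list with $depth_grid and $dose, or
# a two-column matrix; return list(z, d).
.as_depth_dose <- function(curve) {
  if (is.list(curve) && !is.null(curve$depth_grid) && !is.null(curve$dose))
    return(list(z = curve$depth_grid, d = curve$dose))
  m <- as.matrix(curve)
  if (ncol(m) != 2L) stop("curve must have depth and dose columns")
  list(z = m[, 1], d = m[, 2])
}

.interp_at <- function(z, d, z0) stats::approx(z, d, xout = z0)$y

# Trapezoid integral of (z, d) over [a, b] with interpolated end points.
.trapz_between <- function(z, d, a, b) {
  if (b <= a) return(0)
  inner <- z > a & z < b
  zz <- c(a, z[inner], b)
  dd <- c(.interp_at(z, d, a), d[inner], .interp_at(z, d, b))
  sum(diff(zz) * (dd[-1] + dd[-length(dd)]) / 2)
}

# --- depth-dose metrics ----------------------------------------------------

#' Normalize a depth-dose curve to the mid-SOBP reference depth
#'
#' Scales the curve so the dose at the reference depth `zref` equals 100,
#' where `zref` is the midpoint of the proximal and distal 95% points. The
#' 95% points are first located on the raw curve (relative to its maximum),
#' then re-located once after rescaling.
#'
#' @param curve A `sobp_curve`, `pristine_peak`, any list with `depth_grid`
#'   and `dose`, or a two-column (depth mm, dose) matrix.
#' @return The same curve with dose rescaled (dose at `zref` = 100) and the
#'   reference depth stored in attribute `"zref"`.
#' @export
normalize_to_zref <- function(curve) {
  dd <- .as_depth_dose(curve)
  z <- dd$z; d <- dd$d
  if (all(diff(d) >= 0) || all(diff(d) <= 0))
    stop("curve is monotone: no SOBP plateau to normalize to")
  locate <- function(dose, lv) {
    p <- .proximal_crossing(z, dose, lv)
    q <- .distal_crossing(z, dose, lv)
    if (is.na(p) || is.na(q) || p >= q)
      stop("could not locate the 95% plateau bounds")
    (p + q) / 2
  }
  zref <- locate(d, 0.95 * max(d))
  d1 <- d * 100 / .interp_at(z, d, zref)
  zref <- locate(d1, 95)
  d1 <- d1 * 100 / .interp_at(z, d1, zref)
  out <- curve
  if (is.list(out) && !is.null(out$dose)) out$dose <- d1
  else out <- cbind(z, d1)
  attr(out, "zref") <- zref
  out
}

#' Construct a depth-dose QA metrics bundle
#'
#' Holds the standard modulated-beam parameters; `sobp_width` is always
#' computed as `distal95 - proximal95`.
#'
#' @param proximal95,distal95 Depths of the proximal and distal 95% dose
#'   points, mm.
#' @param range90 Distal 90% depth (the beam range), mm.
#' @param penumbra_80_20,penumbra_90_10 Distal falloff widths, mm.
#' @param zref Reference depth, mm; defaults to the 95%-point midpoint.
#' @param homogeneity Longitudinal homogeneity within the SOBP, percent.
#' @param Rp Distal 10% depth, mm.
#' @return Object of class `sobp_metrics`.
#' @export
sobp_metrics <- function(proximal95, distal95, range90 = NA_real_,
                         penumbra_80_20 = NA_real_, penumbra_90_10 = NA_real_,
                         zref = (proximal95 + distal95) / 2,
                         homogeneity = NA_real_, Rp = NA_real_) {
  if (!is.na(proximal95) && !is.na(distal95) && proximal95 >= distal95)
    stop("proximal95 must lie shallower than distal95")
  structure(list(proximal95 = proximal95, distal95 = distal95,
                 sobp_width = distal95 - proximal95, range90 = range90,
                 penumbra_80_20 = penumbra_80_20,
                 penumbra_90_10 = penumbra_90_10, zref = zref,
                 homogeneity = homogeneity, Rp = Rp),
            class = "sobp_metrics")
}

#' @export
print.sobp_metrics <- function(x, ...) {
  cat("<sobp_metrics>\n")
  for (f in names(x)) cat(sprintf("  %-16s %s\n", f, format(x[[f]])))
  invisible(x)
}

#' Field-wise difference of two metric bundles
#'
#' Compares the same parameters measured by two detectors (e.g. a reference
#' plane-parallel chamber against a silicon diode).
#'
#' @param a,b `sobp_metrics` objects; the result is `a - b` per field.
#' @return Named numeric vector of differences.
#' @export
metrics_difference <- function(a, b) {
  stopifnot(inherits(a, "sobp_metrics"), inherits(b, "sobp_metrics"))
  vapply(names(unclass(a)), function(f) a[[f]] - b[[f]], numeric(1))
}

#' Extract modulated-beam QA parameters from a depth-dose curve
#'
#' Normalizes the curve to the mid-SOBP reference depth (dose 100 at `zref`)
#' and reads off the clinical parameters: proximal/distal 95% points, SOBP
#' width, range (distal 90%), distal falloff penumbras (80-20% and 90-10%),
#' the distal 10% depth Rp, and the longitudinal homogeneity
#' `(Dmax - Dmin) / (Dmax + Dmin) * 100` over the SOBP plateau (the curve's
#' declared flat region when it carries one, otherwise the central 80% of
#' the 95%-95% extent, so that the 95%-valued end points do not dominate
#' the ripple). Threshold crossings are located by linear interpolation;
#' proximal thresholds take the shallowest crossing, distal thresholds the
#' deepest.
#'
#' @inheritParams normalize_to_zref
#' @param homogeneity_mode `"diff"` for `(Dmax - Dmin)/(Dmax + Dmin) * 100`
#'   (default) or `"ratio"` for `100 * Dmax / Dmin`.
#' @return A [sobp_metrics()] bundle. Thresholds that are never crossed
#'   yield `NA` with an explanation in attribute `"undefined"`.
#' @export
extract_sobp_metrics <- function(curve, homogeneity_mode = c("diff", "ratio")) {
  homogeneity_mode <- match.arg(homogeneity_mode)
  norm <- normalize_to_zref(curve)
  dd <- .as_depth_dose(norm)
  z <- dd$z; d <- dd$d
  zref <- attr(norm, "zref")
  undefined <- character(0)
  distal <- function(pct) {
    v <- .distal_crossing(z, d, pct)
    if (is.na(v)) undefined <<- c(undefined, sprintf("distal %g%% never crossed", pct))
    v
  }
  p95 <- .proximal_crossing(z, d, 95)
  if (is.na(p95)) undefined <- c(undefined, "proximal 95% never crossed")
  d95 <- distal(95)
  z80 <- distal(80); z20 <- distal(20)
  z90d <- distal(90); z10 <- distal(10)
  # homogeneity is a plateau property: evaluate over the curve's declared
  # flat region when it has one (a designed SOBP), clipped to the 95%-95%
  # extent. Otherwise use the central 80% of [proximal95, distal95] - the
  # closed 95%-95% interval has dose exactly 95 at its end points, which
  # would floor the ripple of even a perfectly flat plateau at ~2.6%.
  hom <- NA_real_
  if (!is.na(p95) && !is.na(d95)) {
    margin <- 0.1 * (d95 - p95)
    lo <- p95 + margin; hi <- d95 - margin
    fr <- if (is.list(curve)) curve$flat_region else NULL
    if (!is.null(fr) && !anyNA(fr)) {
      lo <- max(p95, fr[1]); hi <- min(d95, fr[2])
    }
    inreg <- z >= lo & z <= hi
    Dmax <- max(d[inreg]); Dmin <- min(d[inreg])
    hom <- if (homogeneity_mode == "diff")
      (Dmax - Dmin) / (Dmax + Dmin) * 100 else 100 * Dmax / Dmin
  }
  m <- sobp_metrics(proximal95 = p95, distal95 = d95, range90 = z90d,
                    penumbra_80_20 = z20 - z80, penumbra_90_10 = z10 - z90d,
                    zref = zref, homogeneity = hom, Rp = z10)
  if (length(undefined)) attr(m, "undefined") <- undefined
  m
}

#' Residual range, the proton beam-quality index
#'
#' `Rres = Rp - zref`, with `Rp` the depth at which the dose beyond the SOBP
#' falls to 10% and `zref` the reference (mid-SOBP) depth.
#'
#' @param Rp Distal 10% depth, mm.
#' @param zref Reference depth, mm; must be shallower than `Rp`.
#' @return Residual range in mm.
#' @examples
#' residual_range(30, 12)  # 18 mm
#' @export
residual_range <- function(Rp, zref) {
  if (any(Rp <= zref))
    stop("Rp must exceed zref for a meaningful residual range")
  Rp - zref
}

#' Beam-quality bundle
#'
#' @inheritParams residual_range
#' @return List with `Rp`, `zref` and `Rres = Rp - zref`, class `beam_quality`.
#' @export
beam_quality <- function(Rp, zref) {
  structure(list(Rp = Rp, zref = zref, Rres = residual_range(Rp, zref)),
            class = "beam_quality")
}

# --- lateral metrics -------------------------------------------------------

#' Extract lateral-profile QA parameters
#'
#' Normalizes the profile to 100 on the central axis (x = 0) and computes:
#' field size (distance between the two 50% crossings), `w95` (distance
#' between the outermost 95% crossings), lateral penumbra (mean of the left
#' and right 80-20% edge widths), flatness
#' `(Dmax - Dmin)/(Dmax + Dmin) * 100` within the `w95` region, and symmetry
#' as `100 *` (integral of the left half / integral of the right half) about
#' the field centre (midpoint of the 50% crossings).
#'
#' @param x Position grid, mm (0 on the beam axis), or a two-column matrix.
#' @param dose Dose values on `x` (omit when `x` is a matrix).
#' @param axis_label Optional label ("Y"/"Z") carried into the result.
#' @param flatness_mode `"diff"` (default) or `"ratio"` (`100 * Dmax/Dmin`).
#' @return Object of class `lateral_metrics` with fields `field_size_w50`,
#'   `w95`, `lateral_penumbra_80_20`, `flatness`, `symmetry`, `axis`.
#' @export
extract_lateral_metrics <- function(x, dose = NULL, axis_label = "Y",
                                    flatness_mode = c("diff", "ratio")) {
  flatness_mode <- match.arg(flatness_mode)
  if (is.null(dose)) {
    m <- as.matrix(x); x <- m[, 1]; dose <- m[, 2]
  }
  d0 <- .interp_at(x, dose, 0)
  if (!is.finite(d0) || d0 <= 0)
    stop("profile has no positive dose on the central axis")
  d <- dose * 100 / d0
  c50 <- .crossings(x, d, 50)
  if (length(c50) < 2) stop("fewer than two 50% crossings: not a finite field")
  left50 <- c50[1]; right50 <- c50[length(c50)]
  centre <- (left50 + right50) / 2
  c95 <- .crossings(x, d, 95)
  w95 <- if (length(c95) >= 2) c95[length(c95)] - c95[1] else NA_real_
  edge_width <- function(side) {
    pick <- function(level) {
      cr <- .crossings(x, d, level)
      cr <- if (side == "left") cr[cr < centre] else cr[cr > centre]
      if (!length(cr)) return(NA_real_)
      if (side == "left") cr[1] else cr[length(cr)]  # outermost
    }
    abs(pick(20) - pick(80))
  }
  penumbra <- mean(c(edge_width("left"), edge_width("right")))
  flat <- NA_real_
  if (!is.na(w95)) {
    inreg <- x >= c95[1] & x <= c95[length(c95)]
    Dmax <- max(d[inreg]); Dmin <- min(d[inreg])
    flat <- if (flatness_mode == "diff")
      (Dmax - Dmin) / (Dmax + Dmin) * 100 else 100 * Dmax / Dmin
  }
  sym <- 100 * .trapz_between(x, d, left50, centre) /
    .trapz_between(x, d, centre, right50)
  structure(list(field_size_w50 = right50 - left50, w95 = w95,
                 lateral_penumbra_80_20 = penumbra, flatness = flat,
                 symmetry = sym, axis = axis_label, centre = centre),
            class = "lateral_metrics")
}

#' @export
print.lateral_metrics <- function(x, ...) {
  cat(sprintf("<lateral_metrics> axis %s\n", x$axis))
  for (f in setdiff(names(x), "axis"))
    cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}
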