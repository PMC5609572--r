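---
title: "Methods: beam model, SOBP design and QA metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beam model, SOBP design and QA metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonQA)
```

This vignette documents the physics models, the numerical choices, and the
design decisions behind `protonQA`, in the spirit of a methods section: what
is computed, under which assumptions, and what the synthetic tests do and do
not demonstrate about real beam data.

## Stopping power and range

Protons are slowed with the Bethe formula for the unrestricted electronic
mass stopping power, with no shell or density-effect corrections:

$$ S(E) = K\,\frac{Z}{A}\,\frac{1}{\beta^2}\left[\tfrac12\ln\frac{2 m_e c^2 \beta^2\gamma^2\,T_\mathrm{max}}{I^2} - \beta^2\right] $$

with $K = 0.307075$ MeV cm²/mol and the exact kinematic $T_\mathrm{max}$.
For liquid water we use the ICRU composition values $Z/A = 0.55509$ and
$I = 75$ eV. The omitted corrections matter below ~1 MeV and above
~500 MeV; across the 10–250 MeV window this toolkit addresses, the bare
formula tracks reference water tables to within a few percent, which is the
accuracy class of the whole analytical beam model. Any published table can
be substituted through the table mode of `stopping_power_model()`
(log–log interpolation), which the test suite cross-checks against the
closed form.

The CSDA range is the integral $R(E)=\int dE'/S(E')$, evaluated once per
material as a cumulative trapezoid on a 4000-point log-spaced energy grid
from 0.1 to 300 MeV and then interpolated with a monotone (Hyman) spline in
log–log space. The residual range of a proton below the 0.1 MeV grid edge
is about 2 µm of water and is neglected; for high-Z materials the grid
starts where the Bethe bracket is safely positive, since sub-MeV protons in
tantalum are outside the model's validity anyway. `energy_at_residual_range()`
inverts the *same* interpolant by root finding, so range–energy round trips
are exact to the root tolerance (the suite requires 1e-6 relative) rather
than limited by two independent approximations. Slab degradation
(`degrade_energy`) subtracts each slab's areal thickness from the residual
range in that material — the standard CSDA bookkeeping for thin absorbers.

Units are fixed throughout: energies in MeV, depths and thicknesses of
water-equivalent material in mm, slab thicknesses in µm, stopping power in
MeV·cm²/g or keV/µm.

## The synthetic beam model

`pristine_bragg()` builds a depth–dose curve from the CSDA picture,
$D(z) \propto S(E(R_0 - z))$, convolved with a Gaussian range-straggling
kernel and normalized to a unit peak. The kernel width defaults to the
classical water parameterization $\sigma = 0.012\,R^{0.935}$ mm (about
0.31 mm at the 62 MeV range), exposed as `straggling_factor`. The kernel is
truncated at $\pm5\sigma$, so dose is identically zero beyond the range
plus $5\sigma$; below the phantom surface the entrance value is replicated,
which keeps the entrance dose free of the half-window edge artifact a
zero-padding would cause. A $\sigma$ smaller than the grid step is clamped
to the step, with a warning, to keep the kernel resolvable. The default
depth step is 0.1 mm, matching the scanning resolution of water-phantom
depth–dose measurements; the grid starts at the phantom surface.

What the generator emulates: the range, the peak-to-entrance ratio, the
sharp distal falloff (the generated distal 80–20% penumbra of ~0.45 mm is
close to the ~0.5 mm measured with reference chambers on this class of
beamline), and the behaviour of range-shifted peak families. What it does
not emulate: nuclear attenuation of the primary fluence (the proximal
shoulder of real peaks is a few percent higher), detector volume averaging,
beam-energy spread beyond what the single Gaussian absorbs, and any lateral
coupling — profiles are generated independently as flat tops with
error-function shoulders (`lateral_profile()`, penumbra $=1.683\sigma$).
Tests passing on these curves therefore validate the *metrics and design
machinery*, not a Monte Carlo-grade beam model.

All randomness (profile noise, film noise) is seeded explicitly, and the
generators restore the caller's RNG state.

## Modulator weight design

A modulator wheel realizes a spread-out Bragg peak as a weighted
superposition of range-shifted pristine peaks; the step dwell fractions are
the weights. `design_weights()` solves

$$ \min_{w \ge 0}\ \sum_{z_i \in \mathrm{flat}} \Big(\textstyle\sum_k w_k\,p_k(z_i) - 1\Big)^2 $$

with a hand-written Lawson–Hanson active-set NNLS (the optimizer is the
heart of this module, so it is implemented, not imported; the test suite
validates it against an independent non-negative least-squares
implementation and against exhaustive lattice search on small problems).
Weights are returned in relative mode, with the achieved plateau ripple
attached.

Feasibility is governed by the ratio of step spacing to peak sharpness.
With the default straggling (peak tips of $\sigma \approx 0.31$ mm at
62 MeV), the NNLS-optimal ripple stays under 2% only for step spacings up
to roughly $3\sigma$ (about 0.9 mm); the end-to-end property test uses a
10-step, 0.8 mm-spacing design and verifies ≤2% homogeneity through the
full design → superposition → metric-extraction chain. Wider spacings
scallop the plateau no matter the weights — a 10-step design stretched over
16 mm (1.78 mm spacing) exceeds the 2% target by an order of magnitude —
which is exactly why clinical modulators for full ~16 mm modulation carry
~20 steps. The default spacing in `sobp_peak_family()` is 80% of the
pristine-peak FWHM, a common modulator design rule; an explicit
`modulation_width` overrides it with `width/(n_steps − 1)`.

The air gap of a physical wheel is represented as a zero-thickness first
step carrying the unmodulated (deepest) component. The step-file dialect is
one `thickness_mm weight` pair per line with a `mode:` header; relative
weights that do not sum to one are renormalized with a warning.

## QA metrics and conventions

Threshold crossings are located by linear interpolation between bracketing
samples. On noisy or rippled curves several crossings can exist; proximal
parameters take the shallowest crossing scanning from the surface, distal
parameters and lateral field edges the deepest/outermost one, and
plateau-side lateral thresholds the innermost. Normalization follows the
mid-SOBP convention: the 95% points are located, the dose at their midpoint
$z_\mathrm{ref}$ is set to 100, and the points are re-located once on the
rescaled curve.

Homogeneity is implemented as $(D_\mathrm{max}-D_\mathrm{min})/(D_\mathrm{max}+D_\mathrm{min})\times100$,
with $100\,D_\mathrm{max}/D_\mathrm{min}$ available behind a flag — the
difference-over-sum form is the one consistent with few-percent homogeneity
figures. The evaluation region is a deliberate design choice: the closed
95%–95% interval contains its own end points, where the dose equals 95 by
definition, so ripple evaluated there can never fall below ≈2.6% however
flat the plateau is. `protonQA` therefore evaluates homogeneity over the
curve's declared flat region when it carries one (a designed SOBP), and
otherwise over the central 80% of the 95%–95% extent. Symmetry is the
left/right integral ratio ×100 about the field centre (the midpoint of the
50% crossings), computed with interpolated partial end cells so that
mirroring a profile exactly inverts the ratio. The reference depth for
beam-quality reporting defaults to the SOBP midpoint and can be overridden
(lateral scans are conventionally taken at the fixed mid-SOBP depth).

Metrics reported as undefined (a threshold never crossed) carry the reason
in an attribute rather than failing the whole extraction.

## Dosimetry

`absorbed_dose()` is the reference-dosimetry chain
$D_{w,Q} = M_Q\,N_{D,w,Q_0}\,k_{Q,Q_0}$: an influence-corrected reading
(corrections are labelled multiplicative factors — temperature–pressure,
polarity, recombination — supplied by the user, not computed), the
absorbed-dose-to-water calibration factor, and the beam-quality factor
interpolated linearly on the residual range. Outside the tabulated
$R_\mathrm{res}$ span the function refuses rather than extrapolates:
silent extrapolation of $k_Q$ is a classic commissioning error. No $k_Q$
values ship with the package beyond an explicitly synthetic example table;
real values belong to the user's chamber certificate and protocol.

Output factors are normalized to the 490 mm² reference collimator and
flagged when they drop more than a configurable bound (default 3%,
the commissioning experience for field areas down to ~50 mm²). Pulsed-beam
bookkeeping is the one-liner `dose_per_pulse × rate × 60`.

## Film calibration

netOD is $\log_{10}(I_\mathrm{unexposed}/I_\mathrm{exposed})$ with the film
base folded into the unexposed reference (no separate base-density term).
The calibration cubic maps netOD *to* dose, so converting a scan is
polynomial evaluation; the fit (optionally origin-constrained) must be
strictly increasing over the span of the calibration points, and the
residual RMS is reported as the curve's intrinsic accuracy. The inverse
mapping used by the synthetic film generator seeds a vectorized
interpolation with four Newton iterations, exact to machine precision on
the monotone cubic. Digitization is modelled as integer quantization of
16-bit intensities plus optional seeded Gaussian noise (default 0.2% of
intensity); round-trip accuracy is the fit residual plus one digitization
step, which the suite verifies across the 0.25–4 Gy validity range. The
film response is treated as energy-independent within the residual-range
window of ocular beams (documented validity, not computed). Out-of-range
doses are flagged per pixel, never silently clipped.

## LET

`let_of()` delegates protons directly to the water stopping power
(unrestricted LET); heavier ions use effective-charge scaling
$z_\mathrm{eff}^2 S_p(E/A)$ with the Barkas form for $z_\mathrm{eff}$ — an
approximation adequate for species breakdowns of mixed fields, not for ion
dosimetry. Track- and dose-averages are the first and second
fluence-weighted moments, evaluated at energy-bin centres; halving the bin
width moves the averages by well under 0.5% for smooth spectra. The
Cauchy–Schwarz inequality guarantees $LET_d \ge LET_t$, which the suite
property-tests over a thousand random spectra.

`primaries_let_depth_curve()` represents a beam-energy spread (default
$\sigma_E = 0.3$ MeV, roughly the 0.5% class of a cyclotron beam) by
Gauss–Hermite quadrature over the initial energy; each component slows
independently, so the spectrum at depth narrows and the averages rise
toward the range end. Secondary particles from nuclear interactions are
*not* computed — reproducing the severalfold entrance enhancement of
dose-averaged LET seen in full Monte Carlo requires nuclear physics far
beyond this toolkit. `inject_secondary_component()` lets a user add a
modelled high-LET component and demonstrates the qualitative effect (the
dose average can only rise when higher-LET fluence is added, which the
suite asserts).

## Problem sizes and determinism

The default problem sizes are those of the physical system: 0.1 mm depth
grids over ~35 mm of water (a few hundred points), ten-ish modulator steps,
film maps of a few hundred pixels per side at 150–300 dpi, and LET spectra
of a handful of species times tens of energy bins. Everything runs in
seconds on one core. All file formats are plain text with full-precision
numbers, so write/read round trips are bit-exact, and every CLI report
embeds the package version, the argument echo and its hash; rerunning the
same configuration reproduces reports byte for byte.

## Known limitations

* No nuclear interactions anywhere: primary-fluence attenuation, secondary
  doses and secondary LET are out of scope.
* No multiple-Coulomb-scattering transport: lateral penumbra is a model
  parameter, not a prediction.
* The Bethe implementation omits shell and density corrections; sub-MeV
  behaviour is cut off at the range-table edge.
* Film handling is single-channel (red); multi-channel dosimetry and
  scanner lateral-response corrections are not modelled.
* The dose-rate and RBE conventions of clinical reporting (e.g. the 1.1
  proton RBE factor) are documentation, not computation.
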