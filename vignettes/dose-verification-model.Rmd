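---
title: "The pfxverify dose-verification model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The pfxverify dose-verification model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfxverify)
```

`pfxverify` is an independent second-check dose engine for Leksell Gamma
Knife Perfexion radiosurgery plans. This vignette describes the model it
implements, the parameters that matter and their defaults, the numerical
choices, what the synthetic fixtures do and do not emulate, and the known
limitations. It states no empirical result that the package's test suite
and acceptance script do not themselves compute.

## The machine model

The Perfexion holds 192 Co-60 sources in 8 azimuthal sectors of 24
sources each; within a sector the sources occupy 5 rings at different
polar angles. Each sector is independently set to 16, 8 or 4 mm
collimation, or blocked. `load_machine()` builds this geometry from a
YAML machine definition with sections `geometry`, `beam_data` and
`calibration`; every quantity is in mm, Gy/min or degrees.

The vendor's as-built dimensions and beam data are proprietary. The
shipped default file therefore uses *documented placeholders*: ring polar
angles 35–85° from the frame's superior axis, ring occupancy 4/5/6/5/4
(summing to the 24 sources per sector), physical source-to-focus
distances 374–433 mm per ring, virtual source-to-focus distances (vSFD)
equal to the physical distances plus a small collimator-dependent offset,
and analytic off-axis-ratio tables (below). These values are plausible
for the machine class but are not vendor data; a clinical deployment
replaces the file with commissioned values. Correctness of the engine is
defined with respect to the configured model, which is why every
validation in the test suite is formulated as a closure or symmetry
property rather than a comparison against vendor numbers.

Within each sector the per-ring sources are spread symmetrically over the
sector's 45° wedge, identically in every sector, so the full source set
is invariant under 45° rotations about the machine axis. The test suite
asserts this invariance and uses it: the dose field of a uniformly
collimated shot must be reproduced exactly (to 1e-6 relative) when the
phantom and the calculation points are rotated by 45° about the axis.

The gamma (head-tilt) angle is modelled as a rotation of the machine
frame about the frame's lateral (x) axis by `gamma − 90°`, so 90° is the
identity; 70° and 110° tilt the source hemisphere forward/backward. This
convention makes a 70° shot a 20° tilt away from the neutral position.
Frame coordinates are right-handed Leksell-style coordinates in mm with
the frame centre at (100, 100, 100).

## Skull-surface reconstruction

The patient surface is measured with the frame-mounted skull scaler,
which yields radial distances from the instrument centre along a set of
probe directions. `fit_skull()` expands radius over direction in real
spherical harmonics by least squares. The default degree is 4, i.e. 25
coefficients; the fit refuses to run with fewer measurements than
coefficients and refuses to return a surface that dips to a non-positive
radius anywhere on a dense direction grid. Degree is the one tunable that
matters: degree 2 (9 coefficients) suffices for near-spherical QA
phantoms, degree 4 resolves the anisotropy of a skull-like ellipsoid to
well under a millimetre when ~50+ directions are available, and higher
degrees need correspondingly more measurements. An `even_only` option
restricts the basis to even degrees, which enforces the antipodal
symmetry r(v) = r(−v).

The scaler's standard direction set is instrument-specific and not
published; the fixture generator emits a configurable stand-in (default
24 directions: a quasi-uniform cover of the superior hemisphere plus an
equatorial band, with a small seeded jitter mimicking hand placement).
With 24 directions a degree-4 fit is underdetermined, so phantom
pipelines default to degree 2 (spheres are exact at any degree) or reduce
the degree with a message.

The surface-interpolation scheme is a recognised source of discrepancy
between independent implementations of this kind of engine; a different
smooth scheme fitted to the same scaler data can shift beam entry points
by a fraction of a millimetre and hence focus doses by a fraction of a
percent. This is a modelling choice, not a bug; it is one reason the
clinical comparison works with ±3%/±5% limits rather than exact
agreement.

## Ray tracing

Each of a shot's 192 beams is traced once along its source-to-focus axis.
`ray_entry()` marches from the source in 2 mm steps until the sign of
(distance from the scaler centre − fitted radius along that direction)
flips, then refines the crossing with Brent root finding to a positional
tolerance of 1e-9 mm. The march-then-refine scheme is robust for any
surface that is star-shaped about the scaler centre, which a skull
surface seen from an intracranial centre always is. The tight default
tolerance costs only a few extra bisection steps per beam and keeps
root-finding noise (~1e-9 mm, i.e. ~1e-11 in log dose rate) far below the
1e-10 residual bound used by the attenuation-recovery check; with a 1e-6
mm tolerance that check would be dominated by tracer noise instead of the
physics.

Off-axis calculation points are handled purely by orthogonal projection
onto the traced axis — the depth entering the attenuation term is the
point's own axial depth `d − df`, and no second surface trace is
performed. The alternative reading (re-tracing a parallel ray through
every point) differs only through surface curvature across the beam
width; for cranial geometry and ≤16 mm beams the difference is small, and
the projection form makes the attenuation exponent an identity in the
point's own depth, which the test suite asserts to 1e-12.

Two readings of the source-to-surface distance SSD in the divergence
scaling are defensible; the package defaults to the per-beam constant
`SSD = vSFD − d` (virtual source to skull entry), which is what
"source-to-surface" means physically. The per-point alternative is
available via `options: ssd_convention: point-projection` in the machine
file. At the focus (`df = 0`) the two coincide, so the choice does not
affect focus-dose verification at all, only off-focus grid values, and
then only weakly.

## The dose model

The dose rate at point P from source i is the product of the calibration
dose rate normalised per source (1/192), the collimator output factor,
exponential tissue attenuation `exp(−μ(d − df − R_cal))` with a single
effective linear attenuation coefficient, inverse-square falloff
`(1 − df/vSFD)^(−2)` from the ring- and collimator-specific virtual
source, and the off-axis ratio evaluated at the divergence-scaled
off-axis distance `OAD_f / (1 − df/SSD)`. Defaults: μ = 0.0065 /mm,
R_cal = 80 mm, calibration dose rate 3 Gy/min, output factors 1 / 0.92 /
0.81 for 16 / 8 / 4 mm.

The structure of the model fixes several exact closures that the test
suite and the acceptance script exploit:

* **Calibration closure.** In a spherical phantom of radius R_cal with a
  centred all-open 16 mm shot, every factor except 1/192 is unity, so the
  focus dose rate equals the calibration dose rate (to 1e-9 relative,
  limited only by the tracer). This holds for any radius if R_cal is set
  to it.
* **Output-factor recovery.** At the focus `df = 0` kills the
  inverse-square and divergence factors and `OAD_f = 0` pins OAR at 1, so
  focus dose-rate ratios across collimator sizes equal the configured
  output factors exactly.
* **Attenuation recovery.** The log focus dose rate is exactly linear in
  the phantom radius with slope −μ; a least-squares line over radii
  60–100 mm recovers μ with residuals at the tracer-noise level.
* **Beam-count audit.** An all-open shot is the sum of exactly 192
  per-source terms; one blocked sector removes exactly 1/8 of the rate in
  the azimuthally uniform default geometry.

Degenerate geometry is clamped rather than extrapolated: when
`1 − df/SSD` falls below 1e-9 (a point at or beyond the virtual source,
never reached for physiologic geometry) the divergence scale is clamped
in grid sweeps; the scalar per-source API raises an error instead, since
a caller asking for such a point has a geometry bug. Beams that reach the
focus without passing through tissue contribute zero with a warning; an
all-blocked shot contributes zero with a warning.

## Off-axis-ratio profiles

Two analytic profile families ship with the package. The fixture
generator `make_default_oar()` builds a flat-top profile: unity core of
radius collimator/2, cosine penumbra of configurable width (default
2 mm), zero tail. The shipped machine file instead uses
`make_bell_oar()`: a Gaussian with its 50% level at collimator/2 (FWHM
equal to the nominal collimator size).

The bell shape was chosen for the default deliberately. A perfectly
flat-topped profile makes the single-shot dose maximum *degenerate*: over
the core plateau the only spatial dependence left is the second-order
gain of the attenuation and inverse-square terms toward the beam-entry
side, so the argmax voxel drifts several millimetres off the focus — an
artefact of the profile idealisation, not of the engine. Measured
Perfexion profiles are bell-shaped rather than flat-topped, and with the
Gaussian family the focus is the strict maximum of a single shot, which
is what the geometric-accuracy check (max-dose voxel within 1.5 voxels of
the focus on a 1 mm grid) verifies. Both families satisfy the model's
only hard requirements: OAR(0) = 1 and monotone non-increase. Profiles
are interpolated piecewise-linearly in off-axis distance and clamped to
the last tabulated value beyond the table.

## Plans, durations, grids

A shot carries a frame position, gamma angle, 8 sector states, and a
duration in minutes or a dimensionless weight. When durations are absent
they are derived as `duration = weight × prescription dose / focus dose
rate`, mirroring planning practice where weights apportion the
prescription across shots; with weights 1/n over n shots each delivers
prescription/n to its own focus. The per-shot focus dose reported by
`compute_focus_table()` is the shot's *own* contribution at its focus
(rate × duration): this is the quantity a planning system reports
per-shot and the natural unit for ratio-based verification.
Cross-contributions between shots appear in the 3D grid, not in the
per-shot table.

`compute_dose_grid()` evaluates the plan on its grid spec by computing
each shot's 192 beam traces once and reusing them for every voxel; cost
is linear in shots × voxels with small constants (a 26³ grid at 2 mm
spacing takes on the order of a second per shot on one CPU, which sets
the grid sizes used in the tests: 9³–26³, 1–3 mm spacing). Grids export
to ASCII-encoded NRRD (origin and spacing in the header) and a CSV voxel
dump.

## Verification and reporting

`verify_plan()` joins computed and reference per-shot tables on shot id,
forms computed/reference dose ratios, and flags each shot: pass within
±3%, tolerance within ±5%, action beyond. Deviations exactly at a limit
fall in the less severe category, reading the clinical limits as
inclusive bounds. Both per-shot flags and a plan-level worst-case flag
are reported, since the flagging policy for a plan in which a few shots
exceed the action limit is a clinical decision; the summary carries mean,
sample SD, max and min of the ratios. The HTML report is self-contained
(figures embedded as base64 PNG) and regenerates byte-identically from
identical inputs apart from its timestamp line.

## Synthetic fixtures: what they do and do not show

The fixture module generates sphere and ellipsoid phantoms with exact
analytic scaler radii, stand-in OAR tables, and randomized plans (1–19
shots, matching the shot counts of typical clinical plans; gamma angles
from {70, 90, 110}; random sector states; positions ≥20 mm inside the
phantom surface), all deterministic under a seed. `phantom_surface()`
additionally wraps a phantom spec as an *exact* surface obeying the same
query interface as a fitted one, which is what the closed-form
ray-quadric oracle tests compare against at 1e-3 mm.

Passing these tests shows that the engine implements its stated model
self-consistently and to numerical precision under controlled geometry.
It does *not* show clinical accuracy on real patients: real skulls are
not low-degree spherical-harmonic surfaces, real beam data differ from
the placeholders, and the model itself omits scatter, leakage and tissue
heterogeneity. A site adopting the package must commission the machine
file against measured data and validate against its planning system on
real plans before clinical use.

## Known limitations

* Water-equivalent tissue with a single effective attenuation
  coefficient; no heterogeneity correction.
* No scatter or leakage component, which biases small-field (4 mm)
  absolute doses low; a Monte Carlo engine would be required to capture
  it.
* Star-shaped surfaces only (radius single-valued in direction about the
  scaler centre); CT-derived surfaces are out of scope.
* No source-decay tracking: the calibration dose rate is taken as
  current.
* Placeholder default beam data, as discussed above.
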