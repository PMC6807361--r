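---
title: "Choosing a focal plane for NIR-II neuroimaging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing a focal plane for NIR-II neuroimaging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirmc)
```

## The physical model

`nirmc` simulates light transport in a four-layer, plane-parallel model of
the hairless-mouse head: scalp skin (0.2 mm), skull (0.1 mm),
cerebrospinal fluid (0.1 mm, optically clear) and cortex.  The coordinate
convention is z = 0 at the scalp surface with z increasing downward; all
lengths are cm and attenuation coefficients cm⁻¹.  Two wavelength presets
carry the tissue optics: 785 nm for excitation and 1100 nm for quantum-dot
emission (`default_stack()`, or the YAML presets `mousehead_785` /
`mousehead_1100`).  The 1100 nm stack includes a thin air layer above the
skin so that emission exit angles are evaluated in air, which is what an
objective above the animal sees.

Transport is the standard weighted-photon random walk for layered turbid
media: exponential free paths in `mu_t = mu_a + mu_s`, deposition of the
fraction `mu_a / mu_t` of the photon weight at every interaction,
direction updates from a uniform azimuth and a Henyey–Greenstein zenith
cosine, and unpolarized Fresnel reflection/refraction at layer boundaries
with total internal reflection beyond the critical angle.  Key modeling
assumptions:

* **Flat, laterally infinite layers.**  The real scalp is curved; no
  attempt is made to model that, nor in-layer heterogeneity.
* **Clear-layer anisotropy.**  The CSF and air layers have `mu_s = 0`;
  their tabulated `g = 1` is a no-op marker (a deterministic forward
  "scattering" that never changes the direction).
* **Semi-infinite cortex.**  The cortex slab is at least 1 cm thick and
  its bottom is a perfect sink: photons crossing it are tallied as
  transmitted and never return.  For studies of a stack truncated at a
  plane of interest, `run_transport(ambient_below_n = )` turns the bottom
  into a true refracting interface instead.
* **Unpolarized light, steady state.**  No polarization, coherence or
  time-of-flight information is tracked.

## Fluorescence coupling

The simulation runs in three parts.  First, a pencil beam of 10⁶ photons
enters the skin at 785 nm; the weight entering is reduced by the specular
reflectance `((n1 - n2)/(n1 + n2))²` of the air/skin interface (2.44%).
The on-axis excitation dose at a candidate quantum-dot depth is the
summed weight of *downward* crossings of that plane within a small
on-axis disc, normalized per launched photon and per cm² of disc
(`excitation_efficiency()`).  Second, each candidate depth becomes an
isotropic point re-emitter whose photons inherit an initial weight equal
to the excitation dose relative to the shallowest (0.4 mm) plane; the
preset constants are 1, 0.011, 0.0015 and 0.0005 at 0.4, 0.8, 1.4 and
2.0 mm (`inherited_weight()`).  Third, 10⁶ emission photons per depth are
transported through the 1100 nm stack; every photon leaving the top
surface is recorded with its exit radius, exit angle in air, and residual
weight (`run_emission()`).

Detection applies the microscope geometry (`detector_spec()`): photons
within the acceptance half-angle are kept and binned by exit radius in
0.05 mm sections (`collect()`).  A numerical aperture of 0.25 in air
corresponds to `asin(0.25)` = 14.48°; the bundled preset pins the cone to
exactly 15°, the rounded figure quoted for the instrument this model
represents — both are available.  The Berek depth of field is computed as
`n*lambda/(2 NA²) + n*e/(M NA)`; the magnification `M` and camera-side
resolvable distance `e` are instrument properties with no defensible
universal defaults, so they are explicit inputs and the depth-of-field
value is reported only when they are supplied.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `n_photons` | 1e6 | – | photons per stage; variance scales as 1/sqrt(N) |
| `plane_bin_radius` | 0.005 | cm | on-axis disc for excitation-dose scoring |
| `bin_width` (detector) | 0.005 | cm | radial section width of emission profiles |
| `half_angle_deg` | 15 | degrees | acceptance cone of the objective |
| `roulette_threshold`, `roulette_m` | 1e-4, 10 | – | unbiased termination of faint photons |
| `mode` | `"fresnel_full"` | – | boundary physics (see below) |
| `dr`, `dz` | 0.005 | cm | fluence-grid resolution |

Two boundary modes are provided.  `"fresnel_full"` draws
reflect-vs-transmit decisions from the unpolarized Fresnel reflectance at
the actual incidence angle — the convention of the classic layered-tissue
Monte Carlo codes.  `"paper_eq1"` is a deterministic variant that reflects
only beyond the critical angle and otherwise strips the normal-incidence
reflectance from the transmitted weight; it exists for sensitivity
analysis of the boundary treatment.  The two agree in expectation at
normal incidence (this is tested).

## Numerical choices

* **Random numbers.**  All deviates come from R's global generator; a
  `seed` argument on every driver makes runs bit-reproducible.  Within an
  interaction the draw order is fixed: step, azimuth, zenith, boundary
  decision, roulette.  `simulate_focus_study()` expands one global seed
  into per-stage child seeds by a fixed affine rule, so the excitation
  stage and each emission stage are independently reproducible.
* **Weight ledger.**  Every run partitions the launched weight into
  specular loss, absorbed weight (grid + overflow), top escape, bottom
  transmission, boundary-stripped weight, and *net* roulette loss (gross
  kills minus survivor boosts; Russian roulette conserves weight only in
  expectation, so both sides are tracked).  The identity closes to ≤1e-6
  relative error and is re-validated whenever a ledger is read from disk.
* **Tie-breaks and degenerate inputs.**  A depth exactly on a boundary
  belongs to the layer below.  Planes coinciding with a layer boundary
  are scored at the moment of downward *transmission*, so a photon that
  reaches the boundary but reflects is not counted as having crossed.
  Layers with `mu_t = 0` (vacuum guards) are traversed ballistically.
  `|g| = 1` short-circuits the Henyey–Greenstein inverse CDF to avoid
  division by zero.  Direction cosines are renormalized after every spin
  (drift ≤ 1e-9).  Empty detectors and empty grids yield zero-filled
  results, not errors.
* **Dimensionless step carry-over.**  The unused fraction of a sampled
  step crosses boundaries as `s_left * mu_t`, rescaled by the next
  layer's `mu_t` — the convention that keeps path statistics exact in
  stratified media.

## What the bundled conditions emulate — and what they do not

The presets encode the study conditions this package was built around:
anatomical layer thicknesses of a young hairless mouse, literature tissue
optics at the two wavelengths, a collimated narrow excitation beam, point
re-emitters on the optical axis, and an NA 0.25 macro-zoom collection
geometry.  Passing tests therefore demonstrate correct transport physics
*for this idealized geometry*; they do not capture scalp curvature,
vascular heterogeneity, quantum-dot photophysics (quantum yield,
blinking, spectra), camera noise, or absolute radiometric calibration.

Several scored quantities are strongly **convention-sensitive**, and this
matters when comparing against any externally reported figures:

* The on-axis excitation dose contains a near-ballistic core that is much
  narrower than the default 0.005 cm scoring disc.  Shrinking the disc
  raises the absolute dose without bound (the unscattered beam is a delta
  function in radius) and steepens the depth decay toward the
  Beer–Lambert limit `exp(-mu_t * dz)`; the relative depth profile can
  change by an order of magnitude between a 0.005 cm and a 0.0001 cm
  disc.  The disc radius is therefore an explicit argument, the default
  follows the grid resolution, and relative depth profiles should always
  be quoted together with the radius used.
* Detected radial profiles are reported as summed accepted weight per
  section (the package's contract).  Because section areas grow linearly
  with radius, a per-area reading of the same data is systematically
  flatter-peaked; both conventions can be computed from the returned
  profile.
* Accepted photon *counts* depend on the termination scheme (roulette
  threshold and multiplier) in a way accepted *weights* do not; the
  summary reports both, and the focal-plane recommendation uses weights.

## Problem sizes

The unit and property tests run at 10³–2×10⁵ photons, which keeps the
default suite under a minute while holding 3-sigma analytic oracles.  The
end-to-end reproduction checks and `scripts/acceptance.R` use the full
10⁶ photons per stage — the scale the study conditions specify — and
complete in a few minutes on one CPU.

## Known limitations

Beyond the geometry idealizations above: the fluence grid is cylindrical,
so azimuthal structure is invisible; the QD plane does not absorb or
shadow excitation light; emission is launched from a point rather than
from the laterally extended excited region (the spread of deep detected
profiles is therefore a lower bound); and the simulation is
single-wavelength per stage — no spectral width on either the laser or
the emitter.
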