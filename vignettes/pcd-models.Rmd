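---
title: "Models behind pcdscreen: flow confinement, well transport, nutrient viability and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models behind pcdscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pcdscreen)
```

This vignette is the package's own account of the models it implements:
what each surrogate assumes, which parameters matter, the numerical
choices, and what the tests do and do not establish.  All empirical
statements here are quantities the test suite or `scripts/acceptance.R`
compute; nothing is quoted from elsewhere.

## The system

A pixelated chemical display (PCD) is an open-space microfluidic tip held
a small gap above an immersed surface.  Each of its 3 × 3 fluidic pixels
(6 mm pitch) is fed by one injection aperture at the pixel centre; four
aspiration apertures sit on the pixel corners and are shared between
neighbours, so the display has 9 sources and 16 sinks.  The aspiration
total exceeds the injection total by a factor α = 1.4, which draws
immersion liquid inward and confines each reagent to its own pixel.
Beneath the display, a microwell array holds 3D tumour models — spheroids
or 500 µm microdissected tissues (MDTs) — in 9 groups of 16 wells
(700 µm diameter × 900 µm deep), one group per pixel.

## Gap flow: depth-averaged source/sink superposition

The full 3D laminar flow in the gap is replaced by the standard thin-gap
(Hele-Shaw) reduction: between parallel plates separated by h, the
depth-averaged velocity field of a point source of strength Q is radial
with magnitude Q/(2πrh), and the display's field is the superposition of
all aperture solutions.  The reduction assumes a small gap compared to
the pixel pitch and neglects the microwell openings (the transport module
handles in-well physics; treating the array surface as a flush wall is
consistent with pixel shapes being insensitive to the wells).

* **Gap height h (µm, default 200) and aperture radius (µm, default
  250)** are *declared assumptions* — the source design does not publish
  them — and every flow result echoes the h used.  Velocities scale as
  1/h and wall shear as 1/h², so conclusions are reported as functions of
  h (the acceptance script sweeps h ∈ {100, 200, 500} µm).
* **Wall shear** uses the plane-Poiseuille profile, τ = 6µ|ū|/h, with µ
  the viscosity of water at 37 °C (6.9 × 10⁻⁴ Pa·s).  The pointwise
  supremum sits on the rim of the aperture exclusion disks, so the
  maximum additionally samples rings at one aperture radius around every
  aperture.  At the operating rates (0.5 µL/s per injection aperture,
  α = 1.4) the maximum over h ∈ {100, 200, 500} µm is ≈ 0.14 Pa,
  comfortably below the ~1 Pa regime usually considered safe for
  sensitive cells.  The much smaller printed headline value of the
  original device cannot be checked without the unpublished gap height
  and aperture size; the ≤ 1 Pa bound is the claim this package tests.

### Pixel footprints and the 36 mm² question

`pixel_footprints()` labels each substrate point by the source whose
fluid occupies it, integrating the streamline backwards (midpoint rule on
the unit direction field, step = half a grid spacing) until it enters a
source disk, leaves the truncated bath domain (1.5 pixel pitches beyond
the tip edge), or exhausts its step budget ("unresolved"; in practice a
measure-zero set of separatrix points).

A finite 3 × 3 lattice does not tile into exact 6 × 6 mm footprints.
With the uniform per-sink rates of the `ApertureFlow` contract, the
peripheral sinks aspirate as much as interior ones while serving fewer
pixels, which pulls the basin boundaries outward: the interior footprint
is ≈ 44 mm² at α = 1 and ≈ 39.6 mm² at α = 1.4 (confirmed independently
by the advection–diffusion solve in the D → 0 limit, ≈ 39 mm²).  The
alternative reading — four private corner sinks per pixel, equivalent to
demand-weighted shared sinks — restores exact 36 mm² tiling at α = 1 by
periodic symmetry but undershoots (≈ 32 mm²) at α = 1.4.  The designed
36 mm² therefore bounds the surrogate's interior footprint from the two
sink models to about ±10% at the operating ratio; the package keeps the
uniform-rate contract and reports the areas it actually computes.  The
corresponding acceptance test asserts the 5% design-recovery band and
fails honestly at 39.6 mm².

### Crosstalk

`crosstalk_matrix()` solves the steady depth-averaged advection–diffusion
equation per injected reagent (sources Dirichlet at 1 or 0, sinks
absorbing, bath inflow at 0) with a first-order upwind finite-volume
scheme and alternating-direction Gauss–Seidel sweeps (compiled kernel).
Upwinding adds numerical diffusion of order u·Δx/2; the default 25 µm
grid keeps it at the scale of the physical diffusivity (9 × 10⁻¹⁰ m²/s,
glucose-like) at the operating speeds.

Two crosstalk readouts are distinguished deliberately.  The mean foreign
concentration over a whole footprint necessarily includes the diffusive
smear along the shared 6 mm pixel edges (~1–2% even with the physical
diffusivity), so a 1% footprint-mean threshold is not a meaningful
"crosstalk-free" criterion for any correct solver.  The biologically
relevant readout is the foreign concentration where tissue actually sits:
the microwells, whose centres lie ≥ 0.75 mm inside the pixel boundary.
`crosstalk_free()` therefore averages over the well regions (default) and
declares the checkerboard pattern crosstalk-free below 1% foreign
concentration; at the operating rates the measured maximum is ~10⁻⁵.
The footprint-mean matrix remains available via `region = "footprint"`.

## Well transport

`simulate_well_transport()` solves axisymmetric diffusion in one well
with a tissue seated at the bottom: Dirichlet concentration at the well
mouth, no-flux walls and bottom, symmetry at the axis, concentration
continuous across the medium–tissue interface (one shared field, harmonic
-mean face diffusivities).  Convection inside the tissue is absent by
assumption (dense tumour tissue admits only perifusion); convective
stirring of the upper well can be emulated by a *mixed layer* of depth δ
below the mouth whose diffusivity is inflated 10³-fold.  The default
δ = 0 is the conservative choice: it gives the slowest possible
penetration, so the steady-state time it reports is an upper bound within
the model family.

Numerics: finite volumes on annular cells (default 12.5 µm), backward
Euler in time (one sparse Cholesky factorisation per run; dt = 2 s
default), which is unconditionally stable, positivity-preserving and
satisfies the discrete maximum principle.  An explicit scheme is kept for
cross-checks and refuses steps above 0.25·min(Δr,Δz)²/max(D).  The mass
ledger (mouth influx − uptake − accumulation) closes to solver precision
by construction, and the tests assert closure ≤ 2%.

Oracles: a tissue-free well with radially uniform conditions is exactly a
1D slab, and the bottom concentration matches the Fourier series
t₉₅ = 1.312·L²/D ≈ 1.18 × 10³ s within 5%; a sphere in a well-stirred
bath matches the textbook transient series at Fo ∈ {0.1, 0.3, 0.5}
within 2%.  For these comparisons the analytic radius is taken as
R + Δr/2 because the finite-volume Dirichlet surface sits half a cell
beyond the outermost masked cell — a discretisation convention, not a
tuning knob.

With the reagent diffusivity of glucose in water at 37 °C
(9.0 × 10⁻¹⁰ m²/s, the 25 °C value selectable) in both medium and
tissue, a 500 µm tissue at the bottom of a default well reaches 95% of
the mouth concentration everywhere in ≈ 19.7 min.  This is the model's
account of the platform's 20 min transition time, and the steady-state
threshold (0.95 of mouth concentration over the whole tissue) is a
package decision; the claim being modelled says only "constant
concentration", without naming a percentile.

Dye accumulation is modelled as linear, non-saturating binding,
B = ∫ k·C dt (trapezoidal over stored frames), whose only testable
consequence — longer incubation gives proportionally higher signal, 3 h
vs 2 h ratio 1.5 on a saturated field — is asserted in the tests.  A
saturating option (finite B_max) exists but is off by default.

## Static-culture viability

`simulate_static_culture()` models the nutrient supply of a tissue
between medium changes on a unit cell of the array: one well plus its
share of overlying medium (1000 µm deep, i.e. 400 µL spread over the
~2 × 2 cm slab), with symmetry side walls, as an axisymmetric column of
equal cross-section area.  Oxygen is resupplied at the medium–air
interface (Dirichlet at saturation, 0.2 mol/m³) because the slab material
is gas-impermeable from below; glucose has no resupply (no-flux top) and
only the finite initial reservoir (25 mol/m³).  Each species is solved
independently with Michaelis–Menten uptake in the tissue; survival is
read as the minimum tissue concentration staying at or above Km, taken
over the whole tissue region (a conservative reading of "core").

Uptake is integrated semi-implicitly — the rate Vmax·C/(Km + C_prev) is
Picard-iterated inside each backward-Euler step — so the discrete steady
state solves the true nonlinear balance.  (A simpler operator-split
scheme was rejected: its steady state is biased low by ~dt·Vmax, which at
practical step sizes is larger than the whole oxygen margin.)  The
zeroth-order limit reproduces the steady sphere centre deficit
Vmax·R²/(6·D) within 3%, and the first-order limit the Thiele-modulus
effectiveness factor 3(φ·cothφ − 1)/φ² within 5%.

Default kinetics are literature-style values, declared as package
defaults because the original study's appendix constants are not
published: oxygen D 3.0 × 10⁻⁹ / 2.0 × 10⁻⁹ m²/s (medium/tissue),
Vmax 2.0 × 10⁻³ mol/(m³·s), Km 5 × 10⁻³ mol/m³; glucose D 9.0 × 10⁻¹⁰ /
6.0 × 10⁻¹⁰ m²/s, Vmax 1.5 × 10⁻³ mol/(m³·s), Km 0.5 mol/m³.  The
oxygen Vmax deserves a note: a one-line resistance estimate (supply
through the 1 mm medium column and the 400 µm well constriction into a
500 µm sphere) shows that any Vmax much above ~5 × 10⁻³ mol/(m³·s) makes
the required steady deficit exceed the entire dissolved-oxygen reservoir,
so the core would go anoxic in *any* geometry-faithful model —
contradicting the survival the platform is designed around and reports.
The default is therefore set mid-range of tumour-spheroid oxygen
consumption rates, where the model predicts what the device observes:
at these defaults a 500 µm tissue keeps oxygen ≥ 0.086 mol/m³ and
glucose ≥ 21.6 mol/m³ over 24 h — both above Km, i.e. a daily medium
change sustains the culture.  All defaults are overridable per call and
echoed into every result object.

## Protocols and effective exposure

Schedules are minute-granular event lists (sub-minute events are
rejected; the protocols are specified in minutes).  The transition time —
the ~20 min a freshly switched reagent needs to saturate the tissue,
which is exactly the transport module's t₉₅ above — is deducted **once
per contiguous reagent block** to convert wall-clock streaming intervals
into effective exposures.  This single rule reconciles the TNF timeline
(streaming 20→280 min and 230→280 min) with its nominal 240 min and
30 min exposures, and makes exposure additive under splitting a block at
any interior time.  `validate_schedule()` returns violations as data
(coverage, ordering, single active reagent per group), not exceptions.

## Quantification and statistics

Corrected fluorescence intensity per area is tissue minus background
intensity per area; regions come from mask inputs or the synthetic
generator's ground truth, never from re-segmentation (the original
workflow drew ROIs by hand, which is not reproducible).  Negative
corrected values are possible around zero signal and are flagged, not
clamped.  The nuclear translocation fraction is positive-nuclei area over
total nuclei area, with the positive mask intersected against the nuclei
mask so stray pixels cannot inflate it.

`compare_groups()` implements the platform's statistical contract: a
Kruskal–Wallis omnibus test (via `stats::kruskal.test`) and pairwise Dunn
z-statistics on pooled mean ranks with tie correction, adjusted by
`stats::p.adjust` (default "holm"; the adjustment is configuration and is
recorded in the output, since the original analysis names only the test,
not the adjustment).  Rank-based p-values are invariant under monotone
transforms, which the tests assert, and the null rejection rate at
α = 0.05 over 1000 synthetic seeds falls in [0.02, 0.08].

## Synthetic data: what it does and does not emulate

The generators produce, from a seed and a spec, byte-reproducible
fixtures with machine-readable truth: per-pixel micrographs of up to 16
disk spheroids (foreground = truth FI + background 100 counts, additive
Gaussian noise, 16-bit range), non-overlapping elliptical nuclei masks
whose positive subset hits a target area fraction to within one nucleus,
and per-condition translocation fractions from clamped normals.  Each
generator consumes an RNG stream derived from (seed, call-tag), so adding
generators never perturbs existing fixtures.  The default TNF effect
sizes (0.20 / 0.60 / 0.35 for control / 30 min / 240 min, sd 0.05,
n = 9) encode a transient response — rise then partial decline — and the
tests assert only that the pipeline recovers the *generated* ordering,
not any biological conclusion.

Passing tests on synthetic images show that the quantification arithmetic
is correct under the stated image model; they do not validate against
real optics (no point-spread function, vignetting, 3D stacks, staining
texture or segmentation error — all deliberately out of scope).

## Problem sizes and limitations

Default resolutions (well grid 12.5 µm, unit cell 25 µm, crosstalk grid
25 µm, footprint classification 10 points/mm, dt = 2 s transport / 60 s
viability) were chosen so that halving any of them changes the reported
quantities by well under the tolerances asserted in the tests; the whole
suite runs in a few minutes on one core.  Known limitations: the flow
model is 2D depth-averaged (no vertical structure, no tip-edge 3D bath
entry, hence the ±10% interior-footprint bracket); transient flow
start-up, bubbles and pump dynamics are not modelled; species are
metabolically uncoupled; tissue is non-porous with diffusion-only
interior; photobleaching and dye competition are ignored.
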