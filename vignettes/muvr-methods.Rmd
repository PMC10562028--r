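---
title: "Methods: Monte Carlo monitor-unit verification for VMAT plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Monte Carlo monitor-unit verification for VMAT plans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muvr)
```

## The problem

A treatment planning system (TPS) computes the dose a VMAT plan delivers;
clinical safety practice requires an *independent* secondary calculation of
the dose per monitor unit (MU) before treatment. Commercial secondary-check
products in the modified-Clarkson class compute dose to a single point with
a radiological-depth heterogeneity correction: tissue composition matters
only along the line from the source to the calculation point, so nearby
low-density lung that stays off that line is invisible to them, and
discrepancies in thoracic plans can be large. A voxel Monte Carlo (MC)
calculation transports photons through the whole CT-derived anatomy and has
no such blind spot.

`muvr` implements a desk-scale version of that MC verification pipeline:
DICOM-RT ingestion, HU-based phantom generation, per-control-point source
modelling, photon transport, parallel job splitting with partial-dose
merging, per-energy absolute-dose calibration, DICOM RT Dose export, and a
reference-point evaluation against a 5% action limit — together with a
modified-Clarkson comparator representing the simple-algorithm class.

## Phantom model

CT Hounsfield units map to four materials on contiguous intervals, each
with a linearly interpolated mass-density range:

| Material | HU min | HU max | density min (g/cm³) | density max (g/cm³) |
|----------|-------:|-------:|--------------------:|--------------------:|
| Air      | −1050  | −950   | 0.001 | 0.044 |
| Lung     | −950   | −700   | 0.044 | 0.302 |
| Tissue   | −700   | 125    | 0.302 | 1.101 |
| Bone     | 125    | 2000   | 1.101 | 2.088 |

Decisions the table itself does not fix, made here once and tested:

* **Interpolation inside an interval is linear.** The table gives interval
  endpoints only; linear is the simplest monotone continuous choice and
  matches routine CT-calibration practice. Because interior boundary
  densities agree, the mapped density is continuous in HU.
* **Intervals are half-open** `[HU_min, HU_max)` with the last row closed.
  Only the material label is affected at a boundary; the density is
  identical either way.
* **Out-of-range HU clamp** to the extreme rows' extreme densities (below
  −1050 → Air at 0.001; above 2000 → Bone at 2.088).
* **Resample HU first, then map.** The material index is categorical;
  averaging it would be meaningless, so `build_phantom` interpolates HU
  onto the target grid and maps afterwards.
* A broad Tissue interval puts HU 0 at ρ ≈ 0.980 rather than 1.000. This is
  a property of the published table, not a bug; the calibration factor
  absorbs the absolute scale, and the calibration reference deliberately
  uses a water phantom with ρ = 1.000 (`water_phantom()`,
  `reference_setup()`) because calibration is defined in water.

## Beam model

The geometry convention (ours; vendors differ): patient coordinates in mm
(x left, y posterior, z superior), gantry rotating in the axial plane with
the source anterior at 0°, source-axis distance 1000 mm, no collimator or
couch rotation. Each arc is discretized into control-point *segments*; a
segment uses the circular-mean gantry angle and the linear mean of the jaw
and leaf positions of its two bounding control points (midpoint rule — the
standard discretization of a dynamic delivery), and carries the meterset
increment `beam_mu * (w[k+1] − w[k])`, which telescopes to the arc MU
exactly.

The MLC is an ideal 2-D aperture at the isocenter plane: a ray is either
inside the open region (unchanged) or blocked (weight multiplied by a
single global transmission factor, default 0). Leaf-end curvature,
tongue-and-groove and interleaf leakage of a real HD-MLC are out of scope
because their geometry is proprietary; this is the package's central
simplification on the collimation side and is stated wherever results could
be over-read.

Two source modes exist. The default *parametric* mode samples energies from
packaged toy spectra per energy label (6X, 6FFF, 10X, 10FFF — FFF spectra
are softer, as expected without a flattening filter) and aims rays from the
focal point at uniformly sampled points of the jaw rectangle on the
isocenter plane. The *phase-space* mode consumes files in a documented
fixed-width binary layout (or header-only "sparse" files for count
arithmetic); records are used cyclically, and reuse passes are counted
because re-using a finite phase space adds latent variance that the
statistical uncertainty estimate cannot see.

## Transport physics

The engine is a deliberately small replacement for a general-purpose
condensed-history code, preserving the pipeline's contracts:

* **Photons only, kerma approximation**: at each real interaction the
  energy transferred to electrons is deposited locally. No electron
  transport, so build-up and penumbra are only approximate at interfaces.
* **Woodcock (delta) tracking** across the voxel grid with an
  energy-dependent majorant `max_m (μ/ρ)_m(E) · ρ_max,m`.
* **Interaction sampling** from packaged semi-analytic tables per material:
  Compton from the exact Klein–Nishina cross section times electrons per
  gram; photoelectric from the standard `Z_eff^3.8 / E^3.2` fit normalized
  to water at 10 keV; pair production from a logarithmic threshold fit
  normalized to water at 10 MeV. Compton samples (E′, θ) by rejection on
  the Klein–Nishina angular density; pair production deposits E − 1.022 MeV
  and emits two back-to-back isotropic 0.511 MeV photons; photons below
  10 keV are absorbed on the spot. The water total at 1 MeV comes out at
  0.0706 cm⁻¹ (published value 0.0707), and the tests verify the tables'
  internal consistency rather than any hard-coded constant.
* **Reproducibility**: every history draws from its own splitmix64 stream
  keyed by (run seed, global history index), and histories are assigned to
  segments by largest-remainder allocation of the *total* history count
  over differential MU. Consequently a run split into jobs of any sizes
  reproduces the unsplit run exactly (up to float addition order, tested at
  1e-12), and the same job spec is bitwise reproducible.
* **Uncertainty** is history-by-history: per-voxel sums and sums of squares
  of per-history deposits give `σ_rel = sqrt((⟨d²⟩−⟨d⟩²)/(N−1))/⟨d⟩`;
  voxels never hit are flagged undefined rather than zero.

The 1/√N acceptance test uses 30 mm scoring voxels: with small voxels the
per-voxel event count at N = 10⁴ is so low that the variance estimator is
biased downward and the fitted slope drifts above −0.5 for a reason that
has nothing to do with the engine. The coarse grid keeps the estimator in
its unbiased regime across the whole N range; this choice was made on
estimator-bias grounds, with the acceptance band untouched.

## Calibration

Engine output is in Gy per launched particle. The per-energy calibration
factor is the ratio of TPS to engine dose under the reference condition
(open 10 × 10 cm field, SSD 100 cm, 40 cm water cube, central axis at 10 cm
depth):

```
F_cal = D_tps[Gy/MU] / D_mc[Gy/particle]      (particles per MU)
D[Gy] = D_mc · F_cal · MU
```

The clinical convention quotes TPS output in cGy/MU; the factor of 100 is
applied explicitly (`compute_fcal`). As printed in clinical worksheets the
ratio's unit string is ambiguous; the definition above is the dimensionally
consistent reading and reproduces the intended workflow. Closure is exact
by construction — applying a factor to its own reference run returns the
TPS reference dose at the scoring point — and is tested to 1e-12, as is
invariance to the reference MU (it cancels algebraically).

## The Clarkson comparator

`clarkson_point_dose` represents the commercial single-point class: per
segment, the calculation point is projected to the isocenter plane, 36
sector radii (10°, configurable) are measured from the point to the
aperture boundary (analytically for circular test apertures, by 0.25 mm
radial marching for MLC shapes), and the segment dose per MU is

```
RO · TMR(d_eff) · mean_sectors S(r) · (100 cm / SPD)²
```

with the radiological depth `d_eff` from exact Siddon-style voxel ray
tracing along the source-to-point line. Commissioning tables are analytic
toys — exponential TMR and a saturating scatter factor
`S(r) = 1 − exp(−r/r₀)` normalized at the reference field — so every
Clarkson identity in the tests is closed-form-checkable;
`commission_reference_output` rescales RO against a measured (here:
engine) reference dose, mirroring how such products are commissioned
against clinic dosimetry. The comparator is a *representative* of the
class, not a clone of any product: build-up, off-axis and FFF-profile
handling of commercial implementations are unknown and not emulated. Its
defining property — exact blindness to heterogeneity off the
source-to-point lines — is asserted in the acceptance suite, where the
engine sees the same perturbation at more than 3σ.

## Evaluation protocol

Five reference points per arc inside the PTV: the mask centroid plus four
offsets at 7.5 mm (the midpoint of the 0.5–1 cm convention, configurable
within that band) along ± superior-inferior when the PTV's sup-inf extent
allows (≥ 2·(offset + 2 mm)), otherwise along the lateral axes; offset
points falling outside the PTV are pulled inward along their axis and
flagged. Percent difference is `100 · (D_secondary − D_tps) / D_tps`; the
action limit (default 5%) flags on strict excess with a 1e-9 relative
epsilon so boundary cases do not flag on floating-point rounding. Box-plot
quartiles use R's inclusive linear-interpolation rule (`type = 7`),
documented because quartile conventions differ. Points are evaluated *per
arc* and pooled study-wide (37 arcs × 5 points = 185 in the roster
fixture); pooling per plan is available through `study_summary` grouping.
Doses at points are trilinear interpolations of each grid at the physical
point — neither grid is resampled onto the other, avoiding an undocumented
resampling convention.

## Synthetic data: what it does and does not establish

The fixtures module generates every input: CT series with geometric HU
regions (water, thorax-like, lung-interface recipes), sphere-conformal or
square-field VMAT plans with 98/114/178 control points, structure-set
contours, phase-space files, and TPS-like dose grids. The synthetic TPS
dose is, by default, the package's own engine at high histories with an
optional stated perturbation (e.g. +7% inside the lung mask) — a
deliberate circularity, acceptable because the object under test is the
evaluation logic (point selection, interpolation, flagging, pooling), not
TPS fidelity. The end-to-end acceptance case uses the same seed for the
TPS proxy and the verification run so the MC noise cancels exactly and the
flag pattern is a sharp, deterministic property of the perturbation
geometry. A green end-to-end test therefore establishes that the pipeline
plumbs doses, geometry and statistics correctly; it does not establish
clinical dose accuracy against a real TPS, which would require commercial
software, vendor phase-space files and patient data.

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere a grid is read at a point; no
  extrapolation (points outside a grid are errors, not zeros).
* Zero-MU segments are legal and receive zero histories; zero TPS dose at a
  reference point invalidates that point with a warning instead of
  producing an infinite percent difference.
* RT Dose files store unsigned 16-bit scaled integers with the scale in
  DoseGridScaling; round trips are exact to one quantization step.
* UID remapping during anonymization is a deterministic digest of the
  original UID under a dedicated root, so it is consistent across a file
  set without shared state and idempotent on already-stripped files.
* The phase-space, pardose and 3ddose interchange formats are documented in
  their writers; 3ddose follows the EGSnrc text convention (boundaries in
  cm) for interoperability with existing tooling.

## Known limitations

No electron transport (interface build-up is approximate); ideal-aperture
MLC (no leaf-end or tongue-and-groove effects); toy beam spectra rather
than commissioned ones; identity orientation only; photon-only phase-space
records; no 3-D gamma analysis (single-point and summary statistics only).
These bound what the package can claim: it is a faithful, testable
implementation of the *pipeline* — not a commissioned clinical dosimetry
system.
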