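# muvr — Monte Carlo monitor-unit verification for VMAT arc plans

`muvr` is an independent secondary dose-calculation (monitor-unit
verification, MUV) pipeline for volumetric modulated arc therapy (VMAT)
plans, written for medical physicists and QA-software developers who want a
self-contained, fully testable model of the MC-based secondary-check
workflow.

The treatment planning system's dose is verified by an independent
calculation before treatment. Simple commercial checkers compute dose to a
single point with a modified Clarkson sector integration and an effective
(radiological) depth correction — so tissue heterogeneity matters only
along the source-to-point line, and nearby lung off that line is invisible
to them. A Monte Carlo calculation through the CT-derived voxel anatomy has
no such blind spot. `muvr` implements both sides:

* **DICOM-RT I/O** — CT series, RT Plan (VMAT arcs with per-control-point
  gantry/jaw/MLC/meterset state), RT Structure Set, RT Dose read/write, and
  de-identification with consistent UID remapping.
* **Voxel phantom** — four-material HU lookup (Air/Lung/Tissue/Bone over
  [−1050, 2000] HU) with linear density interpolation per interval and
  clamping outside the table.
* **MC dose engine** (Rcpp) — kerma-approximation photon transport:
  Woodcock tracking, Klein–Nishina Compton sampling, photoelectric and pair
  production from packaged semi-analytic cross sections; counter-based RNG
  keyed by (seed, history) so splitting a run into parallel jobs and
  merging the partial doses (`pardose` → `3ddose`) reproduces the unsplit
  run exactly; history-by-history uncertainty estimation.
* **Calibration** — per-energy factor `F_cal = D_tps[Gy/MU] /
  D_mc[Gy/particle]` (particles per MU) measured under the reference
  condition (10 × 10 cm field, SSD 100 cm, 40 cm water cube, d = 10 cm);
  absolute dose is `D_mc · F_cal · MU`.
* **Clarkson comparator** — per-segment sector integration
  `RO · TMR(d_eff) · mean_sectors S(r) · (100/SPD)²` with exact Siddon ray
  tracing for the radiological depth, representing the simple-algorithm
  class.
* **Evaluation** — five reference points per arc inside the PTV (centroid
  + four 7.5 mm offsets), percent difference `100·(D_sec − D_tps)/D_tps`,
  strict 5% action limit, per-arc and pooled study statistics.
* **Fixtures** — generators for every input (CT recipes, VMAT plan
  recipes, contours, phase-space files, TPS-like dose grids, commissioning
  tables), all deterministic under a seed, so the complete workflow runs
  with no external data.

## Worked example

A synthetic lung case: a thorax-like CT with a tissue/lung interface, a
2-arc VMAT plan conformal to a 25 mm target straddling the interface, a
synthetic "TPS" dose carrying a deliberate +7% error inside lung, and the
MC verification that catches it.

```r
library(muvr)

# 1. synthetic case: CT, phantom, 2-arc VMAT plan
ct      <- make_ct(interface_recipe(spacing_mm = 4), seed = 11)
phantom <- build_phantom(ct)
plan    <- make_plan(plan_recipe(n_arcs = 2, n_cp = 20, energy = "6FFF",
                                 beam_mu = 300, aperture = "sphere",
                                 target_radius_mm = 25),
                     isocenter = c(-16, -8, 0))

# 2. per-energy calibration against the water reference condition
cal <- calibrate_energy("6FFF", d_tps_cgy_per_mu = 0.85,
                        histories = 1e5, seed = 3, spacing_mm = 8)

# 3. synthetic TPS dose with +7% error inside lung, then the MC check
tps   <- make_tps_dose(plan, phantom, cal$fcal, mode = "mc-proxy",
                       perturbation = list(mask = phantom$material == 2L,
                                           factor = 1.07),
                       histories_per_arc = 1e5, base_seed = 21)
check <- simulate_plan_dose(plan, phantom, cal$fcal,
                            histories_per_arc = 1e5, base_seed = 21)

# 4. five reference points in the PTV, 5% action limit
ptv <- array(FALSE, phantom$grid$dims)
co  <- expand.grid(x = grid_axis(phantom$grid, 1),
                   y = grid_axis(phantom$grid, 2),
                   z = grid_axis(phantom$grid, 3))
ptv[(co$x + 16)^2 + (co$y + 8)^2 + co$z^2 <= 20^2] <- TRUE
points <- select_reference_points(ptv, phantom$grid)
report <- compare_doses(tps, check, points)
print(report)
```

which prints (numbers from this exact script):

```
F_cal[6FFF] = 2.52623e+11 particles/MU  (10x10 cm, SSD 100, water, d = 10 cm)
Evaluation report: 5 point(s), action limit 5.0%
  d_tps_gy d_secondary_gy diff_percent exceeds_limit
1    36.97          34.55       -6.542          TRUE
2    46.66          43.61       -6.542          TRUE
3    42.90          40.10       -6.542          TRUE
4    25.85          25.85        0.000         FALSE
5    40.03          37.41       -6.542          TRUE
mean -5.23%  mean|.| 5.23%  sd 2.93%  Q1/Q2/Q3 -6.54/-6.54/-6.54%  exceeding 4/5
```

Reading it: the four reference points inside lung disagree with the
"TPS" by −6.54% (= −7%/1.07, the TPS denominator convention) and trip the
5% action limit; the one point on the tissue side of the interface agrees
exactly. The secondary check localizes the planted lung-region dose error —
the behaviour that motivates MC-based MUV in the first place. A Clarkson
point dose for the same plan is one call:
`clarkson_point_dose(plan, phantom, c(-16, -8, 0), make_tables("6FFF"))`.

## Command line

A thin CLI wraps the main steps (`ingest`, `phsp-concat`, `simulate`,
`merge`, `calibrate`, `check-clarkson`, `report`, `make-case`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","muv.R",package="muvr"))')" \
    make-case --preset lung --out case1 --seed 4
```

## What this package is not

The transport engine is a deliberately small photon/kerma model, not a
condensed-history clinical dose engine; the MLC is an ideal aperture; the
beam spectra are packaged toys, and the synthetic TPS dose is generated by
the package's own engine. See the methods vignette
(`vignettes/muvr-methods.Rmd`) for the model, its assumptions, every
tunable parameter, and what a green test does and does not establish.
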