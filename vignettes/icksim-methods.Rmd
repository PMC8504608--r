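---
title: "Setup-error dosimetry of direct and indirect cell kill: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Setup-error dosimetry of direct and indirect cell kill: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icksim)
```

## The problem

Single-isocenter/multitarget (SIMT) VMAT radiosurgery treats several brain
metastases with one isocenter placed near the geometric centre of all
lesions. Rotational patient setup errors therefore displace each target by
an amount that grows with its distance to the isocenter (chord length
$2R\sin(\theta/2)$ for a rotation $\theta$ at distance $R$), and even
millimetre-scale residual errors can push small, distal planning target
volumes (PTVs) out of the steep peripheral dose gradient.

Tumour control in radiosurgery is attributed to two mechanisms:

* **Direct cell kill (DCK)** — DNA damage in tissue receiving at least the
  prescription dose (20 Gy here);
* **Indirect cell kill (ICK)** — devascularization and intratumour
  immune effects, reported for single doses of roughly 15 Gy and above.

`icksim` quantifies, as a function of a coupled setup-error setting
(*x* mm and *x*° in all six degrees of freedom), how PTV coverage
partitions between the 20 Gy isodose volume (DCK) and the 15–20 Gy band
(ICK), the dose level that still fully covers each PTV (*minimum covering
dose*), the error magnitude at which that covering dose falls below the
15 Gy ICK threshold, and the change in normal-brain radionecrosis risk
via a logistic NTCP model of whole-brain V14Gy.

## The dose phantom

Clinical dose grids come from a treatment planning system and are not
generally shareable, so the package generates synthetic phantoms whose
*calibrated* behaviour matches the published per-magnitude covering-dose
statistics of a real nine-patient, 61-lesion cohort. Each lesion
contributes a radially symmetric, piecewise-linear kernel:

* plateau at $D_\max = \mathrm{Rx}/\mathrm{IDL}$ for $r \le r_\mathrm{GTV}$
  (prescribing 20 Gy to a 70–80% isodose line implies a plan maximum of
  25–28.6 Gy; the default IDL fraction 0.75 is the midpoint);
* linear descent to the boundary dose (default **19.2 Gy**) at the PTV
  surface ($r_\mathrm{GTV}$ + 1 mm margin);
* linear fall-off beyond the PTV surface at the **fall-off gradient**
  (default **3.3 Gy/mm**), clipped at 0 Gy.

The two calibration constants are the core modelling choice. The
unperturbed plans of the emulated study just covered their targets at
19.2 Gy on average, and the covering dose declined through
17.8, 15.9 and 12.6 Gy at error settings of 0.5, 1 and 2 — i.e. by about
3.3 Gy per unit of error setting. Fixing the kernel boundary at 19.2 Gy
and its gradient at 3.3 Gy/mm makes the phantom reproduce that sequence
*when the applied displacement magnitude equals the error setting*. Both
are per-target parameters (`target_spec()`), not hard-wired constants.

Per-target kernels are summed voxelwise (dose is additive; at the
cohort's target separations the cross-target tails are negligible); a
voxelwise-maximum mode exists for sensitivity checks. Masks use
voxel-centre membership with no partial-volume weighting — this matches
contour rasterization at the 1.25 mm study resolution and keeps every
Boolean identity exactly testable. Cohort geometry (lesion counts 2–16,
GTV volumes 0.02–11.5 cc log-uniform, distances to isocenter
2.2–8.9 cm uniform over the sphere) is drawn by seeded rejection
sampling that enforces pairwise PTV disjointness with a two-voxel buffer.

What the phantom does **not** emulate: real plans have anisotropic
gradients shaped by arc geometry and optimization objectives,
inhomogeneous target doses, irregular target shapes, and inter-patient
variability in fall-off. Passing tests on the phantom therefore validate
the *computational machinery* and the calibrated mean behaviour, not the
patient-level standard deviations of the original cohort, which are
flagged as non-reproducible wherever they appear.

## Setup-error transforms

A setup error is a rigid transform about the isocenter: translations
$(\Delta x, \Delta y, \Delta z)$ in mm and rotations pitch (y–z plane),
roll (x–z plane), yaw (x–y plane) in degrees. The composition order of
the three rotations is not physically observable at the simulated
magnitudes (≤ 2° order dependence < 0.01 mm displacement) and is fixed
as pitch → roll → yaw, configurable in `transform6dof()`.

`apply_setup_error()` resamples the dose at inverse-transformed
voxel-centre coordinates with trilinear interpolation: the anatomy and
all masks stay fixed while the dose cloud moves, which is the "replan
with only the isocenter shifted" convention. Samples that leave the
grid are filled with 0 Gy and counted; the clipped fraction is attached
to the result and a warning fires above 1% (configurable). Zero-fill is
deliberate — silent nearest-neighbour extrapolation would hide exactly
the coverage loss this analysis is meant to measure.

**Interpolation error bound.** The kernel is piecewise linear in radius,
so trilinear resampling is exact away from kinks; at a kink with slope
change $\Delta g$ each interpolation pass can err by up to
$\Delta g\, h/4$ at spacing $h$. The dominant kink is the GTV→PTV ramp
($\Delta g \approx 7.5$ Gy/mm at default parameters), giving a
worst-case two-pass round-trip bound of $\Delta g\, h/2 \approx 4.7$ Gy
in a thin shell at the PTV surface, while the bulk error is far smaller
(mean |Δ| < 0.5 Gy on the phantom interior). The test suite asserts
both. This is why covering doses carry a voxel tolerance of
gradient × half-voxel rather than an absolute 0.1 Gy.

## Coverage metrics

All Boolean operations require bit-identical lattices; resampling
happens only in the transform module.

* `isodose_volume(dose, L)` uses the closed threshold dose ≥ L
  ("receiving greater than or equal to"), which makes the partition
  algebra exact.
* `dck_ick_partition()` reports
  $\mathrm{DCK} = 100\,|PTV \cap IDV_{20}|/|PTV|$ and
  $\mathrm{ICK} = 100\,|(PTV \cap IDV_{15}) \setminus IDV_{20}|/|PTV|$;
  their sum is defined to be the V15 coverage fraction so the
  conservation identity holds exactly in floating point as well.
* `min_covering_dose()` implements the iterative Boolean search: raise
  the level in 0.1 Gy steps while the isodose volume still covers the
  PTV. With full coverage required this provably equals the minimum
  voxel dose in the PTV floored to the step lattice, and the suite
  checks that equivalence on 200 random instances. The
  `covered_fraction` knob (e.g. 0.999) exists because one cold voxel at
  1.25 mm dominates sub-0.1 cc targets; the default remains strict
  (1.0) since the step size, not sub-voxel leakage, is the documented
  convention. DVH bins default to 0.1 Gy.

## The error-setting vs displacement convention

The coupled sweep applies "*x* mm / *x*°". Two readings coexist:

1. **six_dof** (default of `error_vector()` and `sweep_config()`): every
   translational component is set to *x* mm and every rotation to *x*°,
   so the translational displacement alone has norm $x\sqrt 3$. This is
   the literal per-axis setting of the emulated workflow.
2. **translation_norm**: a single pure translation of Euclidean norm
   *x* mm. Under this reading the calibrated kernel reproduces the
   published covering-dose sequence exactly as $D(s) = 19.2 - 3.3 s$,
   because the calibration constants were themselves derived from that
   printed sequence with the setting treated as a physical shift.

The package supports both; calibration checks and the acceptance
computation use `translation_norm` (or a directly constructed pure
translation), and reports label the sign assumption, since whether the
original simulations mixed signs is not stated. The headline 1.3 mm/1.3°
threshold is itself independent of this choice: it is the
piecewise-linear crossing of the *published* mean covering doses
(19.2, 17.8, 15.9, 12.6 Gy) with the 15 Gy line, and
`interpolate_threshold()` reproduces 1.27 → 1.3 from those knots with no
extrapolation allowed.

## NTCP model

Radionecrosis risk uses the pooled-literature logistic model
$$\mathrm{NTCP}(V_x) = \frac{1}{1 + (V_{x50}/V_x)^{4\gamma_{50}}},$$
with $x = 14$ Gy, $V_{x50} = 45.8$ cc and $\gamma_{50} = 0.88$ by
default. The exponent $4\gamma_{50}$ is used exactly as published; no
refit is attempted. The function is 0 at $V_x = 0$ by continuous
extension, strictly increasing, equals 0.5 at $V_{x50}$, and satisfies
the log-symmetry identity
$\mathrm{NTCP}(kV_{x50}) + \mathrm{NTCP}(V_{x50}/k) = 1$ — all asserted
in tests. "Normal brain" is the whole brain *with GTVs included*
(the emulated convention); a GTV-excluded mask can be passed instead
where a clinic prefers it. Because a rigid motion conserves dose away
from grid edges, brain V14Gy — and hence NTCP — barely moves under the
simulated errors; both absolute (percentage-point) and relative (%)
differences are reported since both styles are quoted in practice.

## Pipeline, sizes and determinism

`run_sweep()` crosses cohort × magnitudes × sign replicates, producing
per-target coverage records, per-magnitude means ± sample SDs (every
lesion weighted equally; patient-level weighting is a config option),
an NTCP table, and the interpolated threshold. `report()` writes CSVs,
a JSON headline block (threshold, config echo, seed, clipping
statistics) and three figures. CSV/JSON output is byte-identical across
reruns with the same seed; figures are not held to byte identity.

Default problem sizes were chosen to keep a full desk run comfortable:
phantoms for unit tests use brain radii of 20–56 mm (41³–97³ voxel
grids at 1.25 mm), and the calibrated acceptance phantom is a single
8 mm-GTV sphere on a 41³ grid. All randomness flows through explicit
integer seeds (`with_seed()` restores the caller's RNG state), and
cohort sampling, sweeps and reports are bit-reproducible for a fixed
seed.

## DICOM-RT interface

To run on real plan exports, the package includes a deliberately small
DICOM implementation (explicit-VR little-endian only): RT Dose grids
(axis-aligned, uniform frame spacing, 32-bit pixels with
`DoseGridScaling`) and RT Structure Sets with closed planar contours,
both for reading and writing. Contours are voxelized by per-slice
point-in-polygon tests of voxel centres (`mgcv::in.out`), matching the
mask convention of the synthetic phantoms. Frame-of-reference mismatch
and zero/missing dose scaling are hard errors. The round trip
(phantom → DICOM → import) reproduces dose to the scaling quantum and
masks at Dice > 0.98, which is the basis of the import tests. The
subset is *not* a general DICOM reader: multi-orientation grids,
compressed transfer syntaxes and non-planar contours are out of scope.

## Known limitations

* The linear radial kernel cannot represent anisotropic fall-off or the
  dose bridges that form between close lesions in real plans; cohort
  SDs of coverage metrics are therefore not comparable to clinical
  values (means are, by calibration).
* Coverage statistics of sub-0.1 cc targets at 1.25 mm resolution are
  dominated by single-voxel rasterization effects; use finer spacing
  for such targets.
* The 15 Gy ICK threshold is a literature-motivated modelling constant,
  not an output of this package; sensitivity to 70% vs 80% IDL
  normalization is exposed through `idl_fraction` but no claim is made
  about it.
* No beam/arc modelling, no optimization, no deformable registration,
  no TCP or linear-quadratic modelling.
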