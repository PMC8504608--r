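# icksim

Setup-error dosimetry of direct and indirect cell kill for
single-isocenter/multitarget (SIMT) VMAT stereotactic radiosurgery of
multiple brain metastases.

## What it is for

When several brain metastases are treated through one isocenter, residual
patient setup errors — three translations (Δx, Δy, Δz) and three rotations
(pitch, roll, yaw) about the isocenter — displace each target by an amount
that grows with its distance to the isocenter. `icksim` is aimed at medical
physicists and methodologists who want to quantify what those errors cost
in terms of two tumour-kill mechanisms:

* **DCK (direct cell kill)** — the fraction of each PTV still inside the
  prescription isodose volume (20 Gy IDV);
* **ICK (indirect cell kill)** — the fraction inside the 15 Gy IDV but
  outside the 20 Gy IDV, the dose band where single-fraction
  devascularization effects are reported:

  `DCK% = 100·|PTV ∩ IDV₂₀|/|PTV|`,  `ICK% = 100·|(PTV ∩ IDV₁₅) \ IDV₂₀|/|PTV|`.

For each error setting the package finds the **minimum covering dose** (the
highest isodose level that still fully covers the PTV, by iterative 0.1 Gy
Boolean search), interpolates the error magnitude at which that dose drops
below the 15 Gy ICK threshold, and evaluates normal-brain radionecrosis
risk with the logistic NTCP model

```
NTCP(Vx) = 1 / (1 + (Vx50 / Vx)^(4·γ50)),   x = 14 Gy, Vx50 = 45.8 cc, γ50 = 0.88
```

Because clinical dose grids are not shareable, the package ships a
synthetic-phantom generator whose piecewise-linear dose kernels are
calibrated so an unperturbed plan just covers its PTV at 19.2 Gy and the
covering dose falls by 3.3 Gy per millimetre of displacement — the mean
behaviour of the emulated nine-patient, 61-lesion cohort. A minimal
DICOM-RT Dose / Structure Set reader and writer lets the same pipeline run
on real axis-aligned plan exports.

## Worked example

```r
library(icksim)

# one calibrated spherical target: GTV 8 mm, PTV = GTV + 1 mm, 20 Gy to the
# 75% isodose line, boundary dose 19.2 Gy, fall-off 3.3 Gy/mm, 1.25 mm grid
phantom <- build_phantom(list(target_spec(c(0, 0, 0), gtv_radius = 8)),
                         brain_radius = 20)

# sweep pure translations of norm 0 / 0.5 / 1 / 2 mm (the calibrated-
# displacement convention; dof_mode = "six_dof" applies per-axis errors)
res <- run_sweep(phantom, sweep_config(dof_mode = "translation_norm", seed = 1))
res
#> <sweep_result> 4 coverage records over 4 magnitudes
#>   magnitude_mm magnitude_deg n mcd_mean mcd_sd dck_mean dck_sd ick_mean ick_sd
#> 1          0.0           0.0 1     19.7     NA    96.91     NA    3.095     NA
#> 2          0.5           0.5 1     18.0     NA    95.04     NA    4.965     NA
#> 3          1.0           1.0 1     16.2     NA    90.65     NA    9.349     NA
#> 4          2.0           2.0 1     12.9     NA    83.37     NA   13.733     NA
#> 15 Gy-threshold crossing at 1.4 mm/deg (unrounded 1.364)
```

Reading this: with no error the PTV is covered at 19.7 Gy (19.2 Gy boundary
dose plus the half-voxel sampling surplus) and 96.9% of it lies inside the
20 Gy IDV. At 2 mm the covering dose has fallen to 12.9 Gy — below the
15 Gy ICK threshold — while the 15–20 Gy band now carries 13.7% of the PTV:
indirect cell kill partially compensates for the lost prescription
coverage until the error exceeds ~1.4 mm on this phantom.

The headline threshold of the emulated study comes from its published mean
covering doses rather than any phantom:

```r
interpolate_threshold(c(0, 0.5, 1, 2), c(19.2, 17.8, 15.9, 12.6), level = 15)
#> $magnitude          1.272727
#> $magnitude_rounded  1.3
```

i.e. setup errors must stay below **1.3 mm / 1.3°** for every target to
keep at least 15 Gy coverage. Brain toxicity barely reacts to rigid
errors; the model itself gives `100 * ntcp(45.8)` = 50% at the 45.8 cc
half-risk volume and 18.4% at 30 cc.

`report(res, "outdir")` writes the records/summary/NTCP CSVs, a JSON
headline block and the three standard figures. A thin CLI wraps the same
functions: `exec/icksim generate|sweep|analyze --help`-style usage is
documented at the top of that script.

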