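# ventriband

Finite-element simulation of pulmonary valve replacement (PVR) with
**contracting-band insertion** in an idealized bi-ventricular heart, for
computational cardiac-mechanics researchers studying surgical options for
repaired Tetralogy of Fallot.

Repaired-Tetralogy patients often develop right-ventricular (RV) dilation
and a depressed ejection fraction, EF = (EDV − ESV)/EDV × 100, which PVR
alone frequently fails to restore. A proposed augmentation anchors
cable-like bands across the RV cavity whose zero-stress length actively
shortens by a contraction ratio r ∈ {10, 15, 20}% during systole and
relaxes in diastole. `ventriband` builds the whole pipeline:

* **Synthetic geometry** — stacked short-axis contours of a
  truncated-ellipsoid LV with a crescent RV wrapped around it, two wall
  layers, scar/patch labels, and a two-phase pressure waveform; meshed into
  hexahedral elements with layered helical fibers (LV −60°/+80°,
  RV −45°/+40° relative to circumferential).
* **Constitutive model** — anisotropic modified Mooney–Rivlin energy
  `W = c1(I1−3) + c2(I2−3) + D1[exp(D2(I1−3))−1] + (K1/K2)[exp(K2(I4−1)²)−1]`
  with phase-dependent parameters (stiff at end systole, compliant at end
  diastole) and a near-incompressibility penalty.
* **Preshrink + calibration** — zero-load geometry from in-vivo contours
  (inner contours −3%, long axis −3%, outer contours solved for wall-mass
  conservation) and secant calibration of a joint (c1, D1, K1) multiplier
  per phase until simulated RV volumes match the in-vivo EDV/ESV within
  0.2%.
* **Quasi-static solver** — total-Lagrangian Newton iteration with follower
  cavity pressures, selective reduced integration, tension-only band
  cables, and a 0.1% cycle-periodicity stopping criterion.
* **Surgery-plan battery** — five plans (A/B: one band anterior/posterior
  to the mid papillary-muscle level, C = A+B, D: one at the PM base,
  E = A+B+D) × {passive, 10, 15, 20%} plus the no-band baseline: 21 models
  per patient, reported as per-model RV volumes, surface stress/strain, EF
  and ΔEF with cohort mean ± SD summaries and exact Wilcoxon signed-rank
  comparisons.

## Worked example

Build and calibrate one synthetic patient (RV EDV 204 ml, ESV 121 ml, peak
RV pressure 36 mmHg), then compare the three-band plan at 20% contraction
against the no-band baseline:

```r
library(ventriband)
cfg <- synthetic_cohort("P5")[[1]]
pm  <- build_patient_model(cfg)

baseline <- simulate_cycle(vb_model(pm$mesh, pm$materials, pm$pressures,
                                    scales = pm$scales, u0 = pm$u_ed))
baseline
#> <simulation_result> EDV 204.2 ml, ESV 121.2 ml, EF 40.61%, 2 cycle(s), periodicity 7.13e-08

bands <- make_bands("E", pm$mesh, pm$u_ed, pm$u_bf, ratio = 0.20)
e20 <- simulate_cycle(vb_model(pm$mesh, pm$materials, pm$pressures, bands,
                               scales = pm$scales, u0 = pm$u_ed))
e20
#> <simulation_result> EDV 204.2 ml, ESV 108.9 ml, EF 46.67%, 2 cycle(s), periodicity 6.42e-08
```

The calibrated baseline reproduces the in-vivo volumes (EF 40.6%), and the
three active bands cut end-systolic volume from 121 to 109 ml while leaving
end-diastolic filling untouched — an EF improvement of +6.1 percentage
points. A passive band (`ratio = 0`) instead *lowers* EF: it restrains
diastolic filling and cannot relax.

The full battery over a cohort:

```r
battery <- run_battery(synthetic_cohort(c("P1", "P5", "P6")))
summarize_battery(battery)      # cohort mean +- SD per model name
export_battery(battery, "results/")
```

A command-line wrapper lives at `inst/cli/ventriband.R`:

```sh
Rscript inst/cli/ventriband.R --patients P1,P5,P6 --plans A,B,C,D,E \
    --ratios 0,0.10,0.15,0.20 --out results/ --vtk
```

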