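---
title: "Simulating pulmonary valve replacement with contracting bands in an idealized bi-ventricle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating pulmonary valve replacement with contracting bands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patients with repaired Tetralogy of Fallot frequently develop late right
ventricular (RV) dilation and a depressed RV ejection fraction
(EF = (EDV − ESV)/EDV × 100). Pulmonary valve replacement (PVR) alone often
fails to restore RV function. One proposed augmentation is to insert one or
more *contracting bands* across the RV cavity during PVR: cable-like
implants anchored between the free wall and the septum whose zero-stress
length actively shortens during systole (by a contraction ratio r of 10,
15 or 20%) and re-lengthens during diastole. `ventriband` implements a
quasi-static finite-element model of this intervention on an idealized
bi-ventricular geometry, and quantifies the EF change of five band
insertion plans (A: one band anterior to the mid papillary-muscle level;
B: one posterior; C = A+B; D: one at the PM base; E = A+B+D) at four
contraction ratios, against a no-band baseline — a battery of 21 models
per synthetic patient.

Because no patient imaging is distributed with the package, the geometry
module generates an idealized stand-in for segmented cardiac MR: the
per-patient EF values of a real cohort are not reproducible here, but the
*pattern* — passive bands lower EF, active bands raise it monotonically in
r, and three bands beat two beat one — is the quantity of interest, and it
emerges from the mechanics rather than being prescribed anywhere.

## Geometry: an idealized segmented-CMR stand-in

The left ventricle is a truncated ellipsoid of revolution (default
endocardial equatorial radius 22 mm, long semi-axis 48 mm, wall 10 mm),
sliced into 6–14 short-axis contours between 90% of the apex and 50% of
the base direction. The right ventricle is a crescent wrapped around the
LV epicardium: on each slice its cavity lies between a septal arc that
tracks the LV epicardium and a free-wall bulge arc whose height tapers
toward apex and base; the RV wall (free wall 5 mm, septal side 4 mm) is
the closed ring of tissue around that cavity. The crescent bulge is
rescaled by a one-dimensional root find so the Simpson cavity volume
matches a requested RV volume, which lets the synthetic cohort mirror the
reference magnitudes (RV EDV from roughly 200 to 670 ml).

The end-systolic stack is derived from the end-diastolic one by shrinking
the inner contours and slice spacing uniformly (cavity volume scales
exactly with the cube of the linear factor) while the outer contours are
rescaled to conserve wall volume — the same machinery used by the
preshrink step, so wall mass is identical at the two phases by
construction.

What the generator deliberately does *not* emulate: trabeculation and
papillary muscles (band anchor stations are parameterized angular/axial
positions instead), the RV outflow tract, through-wall fiber dispersion,
regional wall-thickness variation, and segmentation noise. Passing tests
on this geometry therefore demonstrates correctness of the mechanics and
of the analysis pipeline, not fidelity to any individual patient anatomy.

## Material model

All tissue components use the modified Mooney–Rivlin strain energy

$$W = c_1(I_1-3) + c_2(I_2-3) + D_1\!\left[e^{D_2(I_1-3)}-1\right]
    + \frac{K_1}{K_2}\!\left[e^{K_2(I_4-1)^2}-1\right],$$

with $I_1, I_2$ the invariants of the right Cauchy–Green tensor
$C = F^\mathsf{T}F$ and $I_4 = n_f^\mathsf{T} C\, n_f$ the squared fiber
stretch. The bundled parameter set (`default_materials()`) carries the
two-phase myocardium values (inner/outer layer, end-ejection and
end-filling), the isotropic patch (c1 = D1 = 26.52 kPa), scar
(13.26 kPa), and band (900 kPa systolic, 70 kPa diastolic) materials, with
c2 = 0 throughout. Two conventions required a decision:

* **Anisotropic exponent.** The energy keeps $K_2$ *inside* the
  exponential, the standard form consistent with $K_2$ being a
  dimensionless constant of order 3. Setting
  `options(ventriband.aniso_k2_inside = FALSE)` switches to the literal
  $e^{(I_4-1)^2}$ variant.
* **Fiber compression.** The fiber term is active only for $I_4 > 1$:
  fibers bear no compressive load.

Near-incompressibility is enforced by a volumetric penalty
$\kappa/2\,(J-1)^2$ with $\kappa = 1000 \times \max c_1$ by default,
together with the classical compressible-Mooney–Rivlin compensation
$-p_0 \ln J$, $p_0 = 2(c_1 + D_1 D_2) + 4c_2$, which makes the reference
state exactly stress-free. Total wall volume change over the cycle stays
below 2%.

Fibers follow the two-layer helix convention: −60° (outer) / +80° (inner)
relative to the circumferential direction in the LV, −45°/+40° in the RV,
assigned per element in the local wall tangent plane.

## Cycle phases and parameter interpolation

The cycle is parameterized by $t \in [0,1)$ with two anchors: *begin
ejection* (BE, maximum cavity pressure, volume = EDV) at $t=0$ and *begin
filling* (BF, minimum pressure, volume = ESV) at $t=0.4$ (the systole
fraction). A single periodic half-cosine weight $w(t)$ (0 at BE, 1 at BF)
drives three things at once, so they stay mutually in phase:

* the pressure waveform (half-cosine decay over ejection, recovery over
  filling; RV peak pressures per patient, default minimum 3 mmHg; LV
  120/8 mmHg — the LV pressures are a modeling default, as only RV
  pressures are catheterization-constrained);
* the myocardial parameters, blended between the *end-filling* rows
  (applied at BE: the muscle is relaxed at end diastole) and the
  *end-ejection* rows (applied at BF: fully contracted at end systole) —
  active contraction enters purely through this parameter switching;
* the band zero-stress-length schedule.

Pressures are converted at the module boundary with
1 mmHg = 0.133322 kPa; 30 time points per cycle is the default sampling.

## Zero-load geometry and calibration

In-vivo contours are pressurized states; the zero-load geometry is
estimated by the preshrink heuristic: inner contours shrink by 3%
(configurable within the physiological 2–3%), slice spacing by 3%, and
the outer contours are rescaled so total wall volume is conserved — the
conservation equation is quadratic in the outer scale factor and solved
in closed form, globally by default (a per-slice variant is available).

Calibration then adjusts one joint multiplier of $(c_1, D_1, K_1)$ per
phase — preserving the published parameter ratios — by a secant iteration
on the log scale until the pressurized RV volume matches the in-vivo
volume within 0.2% relative: the end-diastolic anchor under peak pressure
with the begin-ejection parameter set, the end-systolic anchor under
minimum pressure with the begin-filling set. Because the volume is only
mildly sensitive to stiffness at the low-pressure anchor, the secant takes
up to three refinement steps beyond the acceptance tolerance so the
stiffness scale itself (not only the volume) is pinned; this is what makes
scale self-recovery accurate to better than 1%.

## Band mechanics

Bands are tension-only geometrically exact cable elements (default
cross-section 10 mm²) spanning the RV cavity between endocardial
attachment nodes, sharing wall nodes. The engagement at stretch
$\lambda = \ell/L_0 = 1$ is C¹-regularized over about 1% stretch so Newton
iterations cross the slack/taut transition smoothly.

The zero-stress length follows a two-anchor schedule blended with the same
cosine weight as everything else. In the idealized crescent the free-wall–
septum chord shortens far more over the cycle (≈35%) than a patient RV
chord would, so anchoring the schedule to a single length with the factor
$(1-rw)$ cannot be simultaneously slack in diastole and taut in systole;
the two anchors are therefore tied to the calibrated baseline states:

* **Active band**: diastolic zero-stress length equal to the end-diastolic
  attachment separation (active relaxation — the band exerts essentially
  no force at begin ejection, leaving EDV unchanged to within 1%), and
  systolic zero-stress length $(1-r)L$ with $L$ the in-vivo (begin-
  filling) separation, following the zero-load-length convention of the
  plan catalogue (100%L, 90%L, 85%L, 80%L).
  Its material blends 70 kPa (diastole) to 900 kPa (systole).
* **Passive band**: constant zero-stress length, sized 10% short of the
  end-diastolic separation (a diastolic restraint), with the physical
  900 kPa stiffness all cycle. It is taut at end diastole — lowering EDV
  and hence EF — and slack in systole. The 10% restraint pre-strain is a
  one-time sizing choice of the generator, set with the rest of the study
  conditions.

This asymmetry (material softening + zero-stress lengthening for active
relaxation; neither for the passive implant) is what reproduces the
reference pattern: passive bands *reduce* EF, active bands raise it
monotonically in r without impeding filling.

## Solver

Quasi-static total-Lagrangian equilibrium (inertia dropped: loading is
prescribed-pressure at 30 points/cycle and no density is specified) with
8-node hexahedral elements. The volumetric penalty uses selective reduced
integration — 90% at the element centre, 10% distributed over the 2×2×2
Gauss points to control hourglass modes — which keeps the
near-incompressible response locking-free; the thick-walled cylinder
inflation verification lands within 2% of the incompressible closed form
at this integration rule. Cavity pressures are follower loads with their
exact (nonsymmetric) load stiffness.

Newton's method solves each load state to a relative residual of 1e-6,
with a nonmonotone backtracking line search, adaptive load-increment
bisection, and a polynomial predictor across time steps. The linear
systems use the symmetrized tangent with a cached CHOLMOD symbolic
factorization (sparse LU fallback when indefinite). Boundary conditions:
the basal ring is fixed longitudinally with in-plane freedom, and the
truncated apical ring is clamped as the stand-in for the closed apex; the
two wall bodies are meshed and solved as separate elastic structures (the
septum is a labeled RV-wall region touching the LV epicardium rather than
a shared-node tie) — RV loading is pressure-driven, so the EF analysis is
unaffected by this simplification.

Cycles repeat until the space-time relative L2 difference of the
maximum-principal stress and strain fields over the RV wall between
consecutive cycles falls below 0.1%. Because the model is quasi-static
and history-free this converges at the second cycle (metrics of order
1e-9); the iteration cap remains as an interface contract.

## Reported quantities

For each model the battery reports RV volume, the mean over 100 evenly
arc-length-spaced endocardial sample points per slice of the
maximum-principal Cauchy stress and Green strain, EF, and ΔEF versus the
same patient's baseline, at the BE and BF anchors — the column structure
of the reference result tables. Cohort rows are mean ± sample SD (n−1
denominator, which reproduces the reference cohort SD of 5.53% exactly).
The paired comparison between plans uses the exact two-sided Wilcoxon
signed-rank test (full sign-assignment null distribution; zero differences
dropped, tied ranks enumerated).

## Problem sizes and defaults

The desk-scale defaults — 6 slices, 14 circumferential elements, two
through-wall layers (≈530 nodes / 300 hexahedra per bi-ventricle), 30
time points, three synthetic patients — were chosen so a full 21-model
battery solves in a few minutes per patient on one core while preserving
every qualitative result above; the verification problems (cylinder
inflation, calibration recovery) use their own finer or coarser meshes as
noted in the tests. Because the wall bodies are uncoupled, the battery
computes the LV response once with the baseline and solves band models on
the RV alone.
Doubling the circumferential resolution changes cohort-mean ΔEF values by
a few tenths of a percentage point without affecting any ordering.

## Known limitations

* Idealized geometry: no outflow tract, papillary muscles, trabeculation,
  or per-patient shape variation beyond global size and volume targets.
* Structure-only: no fluid–structure interaction, valve dynamics, or
  isovolumic phases (pressures are prescribed directly at both anchors).
* The LV pressure trace and the band insertion pre-strain are modeling
  defaults, not measured quantities.
* The two wall bodies are mechanically uncoupled at the septal contact.
* Quasi-static: rate effects and inertia are absent, so the periodicity
  check certifies consistency rather than dynamic convergence.
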