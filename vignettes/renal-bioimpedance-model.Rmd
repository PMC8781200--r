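---
title: "Modelling renal bio-impedance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling renal bio-impedance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Renal blood circulation is clinically valuable — for detecting acute
allograft rejection and for managing acute kidney injury — but hard to
monitor continuously at the bedside. Tetrapolar bio-impedance offers a
non-invasive route: two outer electrodes on the posterior skin inject a
small alternating current (3 mA at 100 kHz), two inner electrodes pick up
the voltage, and the transfer impedance `Z = (V(M1) - V(M2)) / I` reflects
the tissue between them. As the kidney fills with blood over the cardiac
cycle its resistivity falls, producing a pulsatile impedance component dZ
of a few tens to hundreds of milliohms. Whether that component is actually
dominated by the kidney — rather than by the fat and muscle above it —
depends on electrode spacing, kidney depth, and intrarenal blood
distribution. This package provides a patient-specific forward model to
answer that question before a measurement is made.

## The model

**Geometry.** The trunk is an elliptic cylinder (defaults: axes 253.7 x
166.71 mm, measured from MRI of the reference subject) extruded 400 mm
along the body axis. Moving inward from the posterior skin the body wall is
subcutaneous fat (5.54 mm) and muscle (10.74 mm); the remaining interior is
homogeneous abdominal background. The kidney is a two-layer ellipsoid —
a cortex shell of uniform thickness 5 mm around a medulla core — wrapped in
a perirenal fat capsule and placed at a configurable depth below the skin.
Everything is voxelized on a regular grid (labels sampled at voxel
centres); the voxel size must not exceed the cortex thickness, otherwise
the shell would be unresolvable.

The kidney's own dimensions, its depth, its lateral offset, and the capsule
thickness are not published for the reference subject; they are exposed as
plain config values. The defaults are: semi-axes (45, 25, 15) mm — a
low-normal adult kidney — depth 26.28 mm (wall thickness plus a 10 mm
capsule), lateral offset 60 mm. The kidney size deserves a note: with the
published 5 mm cortex shell, a large kidney makes the *medulla* the
majority of kidney volume, which is anatomically wrong (renal parenchyma is
cortex-dominant) and inverts the sensitivity ordering of the perfusion
cases below. The low-normal default keeps the cortex at ~53% of kidney
volume, the closest a 5 mm two-layer ellipsoid gets to real anatomy at
adult scale.

Skin is not modelled as a separate layer (the published layer table starts
at subcutaneous fat); electrode disks (3 mm diameter) sit directly on the
fat surface. The four electrodes are in line along the body axis over the
kidney projection: current pair outermost at separation `3 d`, measuring
pair innermost at separation `d`.

**Tissues and perfusion.** At 100 kHz the resistive component dominates
tissue impedance, so the solve is purely real. Kidney cortex and medulla
start at 5.84 Ohm·m. The remaining tissues (subcutaneous and perirenal fat
40, muscle 2.8, blood 1.5, abdominal background 5.0 Ohm·m) are
literature-derived in-vitro values at 100 kHz, not measured for the
subject, and are config values. Blood filling is mapped to resistivity by
the parallel-conductor model: tissue of mass `m_k` and resistivity `rho_k`
receiving blood mass `m_b` of resistivity `rho_b` drops by

    delta = rho_k * m_b * (rho_k - rho_b) / (m_k * rho_b + m_b * rho_k).

One cardiac cycle of healthy renal perfusion (400 mL/min per 100 g, about
6.67 g of blood per 100 g of tissue per second-long cycle) gives
`delta ~ 0.89 Ohm·m`, the "approximately 1 Ohm·m" scale of dynamic renal
resistivity change. Two canonical blood-distribution cases are built in:
90–10 (normal, cortex receives 90% of flow; cortex 5.84 -> 4.99, medulla
5.84 -> 5.75 Ohm·m) and 70–30 (reduced cortical perfusion; 5.84 -> 5.18 and
5.84 -> 5.56). These after-values are used verbatim as the case
definitions rather than re-derived, because the blood/layer mass split
behind them is not published; the parallel-conductor relation remains
available for user-defined cases.

**Forward solve.** The quasi-static conduction equation
`div(sigma grad phi) = 0` is discretized by a 7-point finite-volume stencil
with harmonic-mean face conductivities (exact for layered media normal to
the face, the dominant structure here). All outer boundaries are
insulating; the current electrodes inject a uniform current density over
their rasterized disk footprints; measuring electrodes are ideal
(area-averaged potential, no shunting — the complete-electrode model is out
of scope for lack of contact data). The potential gauge is zero mean over
the conduction domain. The singular, consistent Neumann system is solved
matrix-free by Jacobi-preconditioned conjugate gradients (relative
residual 1e-8, cap 1e5 iterations) in compiled code; the constant null
vector is annihilated exactly in floating point by the stencil, so CG
stays on the range of the operator. Solves are deterministic and
bit-reproducible.

## Numerical choices and validation

**Analytic oracles.** For point electrodes on a homogeneous half-space the
symmetric in-line array has the closed form `Z = 2 rho b / (pi (a^2 -
b^2))` (`a`, `b` half the current / measuring separations); the
equidistant array reduces to the Wenner value `rho / (2 pi d)`. A
homogeneous block 304 mm wide (5x the current span at d = 20 mm) solved at
h = 2 mm matches the half-space value within ~1.6%.

Grid-refinement convergence is asserted against
`analytic_tetrapolar_box()`, the exact continuum solution of the *same
finite block* computed by the method of images and evaluated at the
realized (rasterized) electrode columns. This matters for two reasons
found during validation: the insulating walls of a desk-scale block
contribute about +1% to Z, so the pure half-space value is not the h -> 0
limit; and the rasterized footprint positions shift slightly with h, which
dominates the h-dependence unless the reference tracks them. Against the
matched reference the error falls monotonically (about 0.05%, 0.01%,
0.0001% at h = 4, 2, 1 mm).

A second, independent route checks the compiled solver itself: on small
grids the same operator is materialized as a sparse matrix
(`conduction_matrix()`) and solved directly via a Cholesky factorization
with one grounded node; both routes agree to solver tolerance.
Reciprocity (swapping current and measuring pairs) holds to ~1e-8 on the
heterogeneous patient model, far inside the 0.1% validity requirement.

**Sweeps.** The spacing protocol is d = 7 to 40 mm in 3 mm steps. By
default each row adapts its grid as `h = min(2, d/4)` mm so small arrays
keep at least four voxels per spacing; a fixed `h` can be forced, and the
trend tests use a reduced protocol (4 spacings at h = 2.5 mm, about 1.1M
voxels per solve) to keep a full run on one CPU in minutes. Sweep rows are
independent; an infeasible row yields NA with a warning rather than
aborting. Tables carry a model identifier so results from different
configs are not silently compared. Absolute impedance values are *not*
comparable with the published simulation (whose kidney geometry, non-renal
resistivities and electrode boundary condition are unpublished); the
published trends are: static Z strictly decreasing in d, pulsatile dZ
non-decreasing in d, dZ(90–10) >= dZ(70–30) at every d, and dZ attenuating
as the kidney deepens. All four are reproduced. One published sweep-table
cell (22 mm, 70–30 column) violates that table's own monotone pattern and
is treated as a typo; it takes no part in any comparison.

**Pulsatile waveform synthesis.** `simulate_impedance_waveform()` drives
the layer resistivities from a blood-volume curve Q(t): layer blood mass is
taken proportional to Q, scaled so the cycle maximum reaches the case's
blood-filled resistivities (inverting the parallel-conductor relation),
and dZ is interpolated between `n_keyframes` solved filling levels.
Because the perturbation is small (dZ/Z ~ 1e-3) the response is almost
exactly linear: 5 keyframes differ from 2 by well under 5% of the peak, so
the cheap 2-keyframe mode (`dZ(t) = dZ_max * Q(t)/max Q`) is the default.

**Doppler volume pipeline.** Per-cycle kidney blood-volume change is
`Q(t) = int_0^t Va*Sa - int_0^t Vv*Sv` (vessel cross-sections: artery
0.30 cm^2, vein 0.38 cm^2), integrated by the trapezoid rule — second
order, exact for piecewise-linear traces; Q(T) converges at O(dt^2) as the
tests verify. Velocity inputs are spatially averaged traces over one
cardiac cycle; multi-cycle segmentation is out of scope. Series on
different time bases are linearly interpolated onto a common 500 Hz grid
(the impedance acquisition rate) before the Pearson correlation is taken.

## The synthetic generators

The measured Doppler curves exist only as figures, so the generators
emulate their shape: the artery is a diastolic floor plus a half-sine
systolic peak, the vein a modulated constant. Defaults (floor 18, peak 67,
systole 35% of a 1 s cycle) are set so the per-cycle arterial volume is
~8.7 cm^3 — the renal stroke volume implied by 400 mL/min per 100 g scaled
to a typical 130 g kidney; the venous mean (22.8 cm/s) returns the same
volume through the larger vein. (The voxel kidney is low-normal sized for
the geometric reason above; the generator represents typical total renal
flow, and both are config values.) Noise is additive Gaussian only —
seeded, so all generators are bit-reproducible, and changing only the seed
changes only the noise realization. Physiological baseline wander,
respiratory kidney motion and device effects are deliberately absent:
passing tests show the pipeline recovers a known ground truth, not that it
is robust to every artefact of a clinical recording.

With noise at 20% of signal sd the expected volume/impedance correlation
is `1/sqrt(1 + 0.2^2) = 0.981`; across 200 seeds at 500 samples the
observed r falls within [0.96, 0.995] for at least 95% of seeds,
bracketing the ~0.9 agreement
reported between measured impedance and Doppler-derived volume without
reproducing its exact value (raw in-vivo signals and their alignment are
not recoverable).

## Known limitations

- Absolute impedances depend strongly on the under-specified electrode
  boundary condition and non-renal resistivities at small spacings; only
  trends are validated.
- The two-layer ellipsoid kidney cannot simultaneously match a published
  5 mm cortex and the real ~70% cortical volume fraction; the default
  compromises at ~53%.
- Purely resistive solve at a single frequency; no reactive component,
  electrode polarization, or contact impedance.
- One-direction respiratory displacement only (depth increase); no liver
  or spleen confounders; no unstructured meshing of true organ shapes.
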