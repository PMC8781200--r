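# renalimp

Patient-specific forward modelling of renal electrical bio-impedance.

Renal blood circulation is clinically important — acute allograft
rejection and acute kidney injury both show up in it first — but hard to
monitor continuously. A tetrapolar (four-electrode) array on the posterior
skin can sense it: the outer pair injects a small 100 kHz current, the
inner pair picks up the voltage, and the cardiac-cycle modulation of the
transfer impedance dZ tracks kidney blood filling. Whether dZ is really
dominated by the kidney depends on electrode spacing, kidney depth and
intrarenal blood distribution. `renalimp` answers that design question in
silico, for a specific patient geometry, before any electrode is attached.

The package is aimed at biomedical-instrumentation researchers designing
renal impedance-plethysmography measurements.

## What it computes

* **Voxel model of the perirenal space** — layered elliptic-cylinder trunk
  (subcutaneous fat, muscle, abdominal background), two-layer kidney
  ellipsoid (cortex shell + medulla) in a perirenal fat capsule, disk
  electrodes rasterized on the skin (`build_patient_model()`).
* **Perfusion-to-resistivity mapping** — the parallel-conductor model
  `Δρ = ρ_k m_b (ρ_k − ρ_b) / (m_k ρ_b + m_b ρ_k)` and the canonical
  90–10 / 70–30 cortex–medulla blood-distribution cases
  (`parallel_conductor_delta()`, `apply_perfusion_case()`).
* **Quasi-static forward solve** — matrix-free finite-volume conjugate
  gradients for `∇·(σ∇φ) = 0` with harmonic-mean face conductivities and
  uniform current injection over the electrode footprints; tetrapolar
  transfer impedance `Z = (φ̄(M1) − φ̄(M2))/I` (`solve_tetrapolar()`), with
  analytic half-space and finite-box oracles (`analytic_tetrapolar()`,
  `Z = 2ρb/(π(a²−b²))`, and `analytic_tetrapolar_box()`) plus a
  reciprocity check.
* **Measurement protocols** — electrode-spacing sweeps (d = 7…40 mm,
  current pair at 3d), kidney-depth sweeps, and time-resolved pulsatile
  waveform synthesis (`spacing_sweep()`, `depth_sweep()`,
  `simulate_impedance_waveform()`).
* **Doppler blood-volume pipeline** — per-cycle kidney volume change
  `Q(t) = ∫ V_a S_a − ∫ V_v S_v` from renal artery/vein velocity traces and
  its Pearson correlation against the impedance waveform
  (`blood_volume_change()`, `pearson_correlation()`).
* **Synthetic data** — seeded generators for Doppler-like velocity pairs
  and ground-truth impedance waveforms, plus the reference patient fixture
  (`synth_velocity_pair()`, `default_patient()`).

## Worked example

```r
library(renalimp)

p <- default_patient()          # trunk 253.7 x 166.71 mm, kidney at 26.3 mm

# pulsatile impedance for normal vs reduced cortical perfusion
tw <- spacing_sweep(p$torso, p$kidney, p$tissues, cases = p$cases,
                    d_values = c(7, 16, 25), h = 2.5)
tw
#>   d_mm Z_before_ohm Z_after_90-10_ohm Z_after_70-30_ohm dZ_90-10_ohm
#> 1    7    547.61085         547.59936         547.60015   0.01149645
#> 2   16    105.29765         105.25570         105.25827   0.04194781
#> 3   25     37.73718          37.67897          37.68203   0.05821040
#>   dZ_70-30_ohm
#> 1   0.01070616
#> 2   0.03937989
#> 3   0.05515242
```

Static impedance falls steeply with electrode spacing (larger arrays see
deeper, more conductive tissue), while the pulsatile component dZ grows —
at 25 mm spacing the kidney signal is ~5x stronger than at 7 mm, and the
normal-perfusion case (90% of blood to the cortex, nearer the electrodes)
always yields a larger dZ than reduced cortical perfusion. That is the
design rationale for kidney-sized arrays (spacings of 20 mm and more).

```r
# Doppler verification path: volume change over one cycle, then correlation
w <- synth_velocity_pair(waveform_params(seed = 7))
Q <- blood_volume_change(volumetric_flow(w$artery), volumetric_flow(w$vein))
dz <- synth_impedance_from_volume(Q, gain = 1,
                                  noise_sd = 0.2 * sd(Q$Q_cm3), seed = 8)
pearson_correlation(Q, dz)
#> [1] 0.9798901
```

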