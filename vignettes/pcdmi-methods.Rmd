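---
title: "Signal models and processing methods in pcdmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signal models and processing methods in pcdmi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcdmi)
```

# Scope

`pcdmi` models and processes spectral–spatial deuterium (²H) acquisitions
at 9.4 T: a FISP-based chemical-shift-imaging (CSI) reference protocol and
two phase-cycled balanced-SSFP (bSSFP) variants with CSI and multi-echo
(ME) encoding. This vignette records the models, the conventions the
package commits to where the underlying physics admits more than one
defensible choice, and the limits of what the synthetic tests demonstrate.

# Steady-state signal models

The balanced steady state of one resonance is the classic single-pool
expression in the per-TR phase `Φ = 2π(Δf_j + Δf₀)TR` and
`θ = Φ − ψ` (ψ the RF phase increment per TR), multiplied by `e^{−t/T₂}`
decay and `e^{i(t/TR)Φ}` phase evolution during the TR. It is validated in
the test suite against an independent Bloch simulation (explicit rotation
matrices, RF phase schedule and receiver demodulation, iterated to the
periodic steady state) to 1e-4 over a random parameter sweep.

The FISP (SSFP-FID) amplitude is the closed form equal to the complex
isochromat average of the balanced steady state over one cycle of uniform
intravoxel dephasing — the physical effect of the unbalanced spoiler —
and is likewise checked against an isochromat simulation.

Both models are single-compartment and ignore diffusion damping of
higher-order configurations, finite RF pulse duration (rectangular pulses
are assumed ideal) and magnetization transfer.

# Signal efficiency: conventions

Protocol SNR comparisons use `efficiency = amplitude × readout factor /
√TR`, SNR per unit scan time for a fully relaxed M₀ of one. Three
conventions needed fixing:

* **Readout decay constant.** The FISP FID dephases irreversibly at the
  voxel level, so its matched-filter readout factor
  `sqrt(∫ e^{−2t/τ} dt)` uses `τ = T2*` from the start of the free
  induction decay. In a balanced sequence the gradient-recalled readout
  refocuses the reversible dephasing, so the steady-state T₂ term of the
  signal model governs the decay; bSSFP readout windows are centered in
  the TR (one contiguous window for CSI encoding, `n_echoes` windows of
  width `TR·duty/n_echoes` at the echo centers for ME).
* **Phase-cycle combination.** The K phase-cycled acquisitions are
  combined matched-filter style, `sqrt(mean_k |S(ψ_k)|²)`; with K = 1
  this is the single 180°-increment signal.
* **Off-resonance handling.** By default the root-mean-square is
  additionally averaged over a uniform off-resonance spanning one banding
  period (`df0 = "average"`). The protocols are designed for a
  whole-brain B₀ span of ≈210 Hz — several banding periods at TR 19 ms —
  so the uniform average is the design-relevant operating condition.
  `df0 = "centered"` evaluates each metabolite at its own resonance
  instead; both are exposed because the choice is not uniquely determined
  by the protocol definition.

Under these conventions the shipped presets give a glucose efficiency
gain of ≈ +48 % and a Glx gain of ≈ +63 % for CSI-PC-bSSFP over the
standard CSI, a worst-case ME-vs-CSI-PC decrease of ≈ 5 %, and an in vivo
water change of ≈ −14 % (water's low T₂/T₁ ratio does not favor bSSFP at
these flip angles; phase cycling costs a further ≈ 20 % for
passband-centered spins). For the long-T₂ phantom water the same models
predict ≈ +54 %, which is of the order of phantom measurements reported
for such protocols; substantially larger phantom gains would require a
combination rule without the `1/√K` phase-cycling penalty, which we do
not consider physically consistent.

The SAR model is a single scalar: time-averaged power
`P = c · flip² / (dur · TR)` with the shipped calibration constant
`c = 0.125 W·ms²/deg²` chosen so the three presets sit just inside the
12 W limit typical of this coil class. No tissue model is implied.

# Reconstruction in SNR units

Raw data are noise-prewhitened with the inverse Cholesky factor of the
sampled channel covariance. Acquisition weighting is stored as averaged
k-space with per-point noise variance `1/w`; after zero-padding to twice
the matrix and a unitary FFT the uniform image-noise variance is
`Σ(1/w)/P_pad`, and dividing by its square root yields exactly unit
background noise SD. Adaptive coil combination uses per-voxel unit-norm
matched-filter weights from the sample-and-cycle-averaged volume
(block size one voxel — the smallest-bias choice at these matrix sizes),
applied identically to every echo and cycle, preserving SNR units.

One caveat is intrinsic to the method: in voxels with no signal the
combination weights align with the noise itself and inflate the apparent
background SD by a few percent (the weights are rank-one estimates from
the averaged volume). The unit-SD contract is therefore verified on the
single-channel path, where the weights reduce to a pure phase, and the
multi-channel behaviour is verified through its √2 two-channel SNR gain.

# Spectral separation

*Standard IDEAL* estimates per voxel a common off-resonance and complex
amplitudes by variable projection. Because a shared Δf₀ merely
demodulates the data, the residual can be evaluated for all voxels at
once: a 1 Hz grid over the search band followed by a vectorized
golden-section refinement (40 iterations, interval 2 Hz, i.e. sub-mHz).
For bSSFP data the search band is one aliasing period
`(−1/(2TR), 1/(2TR)]` and estimates are wrapped into it; the FISP-CSI
readout identifies Δf₀ over the much wider spectral bandwidth, so a
±150 Hz default band is used there. The design optionally includes the
known per-metabolite decay envelope (`decay = "T2"`/`"T2star"`): for B₀
estimation ahead of the linear fit this removes a small (≲0.5 Hz)
decay-induced bias that otherwise propagates into metabolites whose
in-band frequency aliases close to water.

*IDEAL-modes* applies a unitary-scaled DFT along the phase-cycle axis
(`F₀` = complex cycle mean; orders `|c| ≤ K/2 − 1` retained), fits each
configuration order with the phase-evolution-only model (relaxation
deliberately omitted — this is what makes the method robust to unknown
relaxation times), and combines the per-mode amplitudes with the
principal eigenvector of the mode covariance over the masked voxels,
estimated per metabolite, unit-norm, and phase-anchored so the `c = 0`
weight is real-positive. Voxels below three noise SDs of water amplitude
are excluded from the covariance by the caller's mask. The combination is
SNR-optimal for a rank-one mode profile; the weights track the simulated
mode-decay profile (correlation > 0.9 in the tests).

*Linear fit* solves the `(N·K) × M` system whose columns are the full
bSSFP model at the voxel's Δf₀. Voxels are grouped by Δf₀ quantized to
0.25 Hz so each design is factorized once; condition numbers are recorded
and voxels with cond > 1e8 flagged. Neglecting the T2 decay in
IDEAL-modes biases amplitude ratios on full-model data; with the
long-T₂ phantom spins this bias is within 5 %, while for short-T₂ in vivo
spins at unfavourable off-resonances it can reach ~10–20 % — which is why
absolute quantification goes through fitter-consistent calibration
factors (below) rather than raw amplitudes.

All fitted maps carry the Euclidean norm of their complex combination
coefficients (`snr_scale`); `scale_to_snr()` divides by it so unit-noise
input yields unit-noise metabolite maps.

# Relaxometry

Inversion-recovery and spin-echo series are fitted as 2-D
(frequency × time) surfaces: one three-parameter Lorentzian per
resonance times `a(1 − b e^{−TI/T1})` or `a e^{−TE/T2}`, with complex
amplitudes solved linearly inside a Levenberg–Marquardt refinement of the
nonlinear parameters (variable projection), multi-started at ±0.2 ppm on
the center frequencies. `b` is bounded to `[0, 2.2]` to absorb imperfect
adiabatic inversion. Ventricular water is modelled as a second linear
component sharing the lineshape with its own T₂; its amplitude fraction
is the reported long-T₂ fraction. The water lineshape deviation from
Lorentzian seen in strongly inhomogeneous fields is out of model. The
estimator variance of T₁ at spectral SNR 100 is verified to sit at the
Cramér–Rao bound within sampling error of 100 draws.

# Quantification

Concentrations follow
`conc_j = |amp_j|/|amp_water| / cal_j · 10.12 mM · n_water/n_j`, with Glx
divided by `1 − 0.33` for the label loss in oxidative transformation.
The calibration factor `cal_j` is computed by forward-modelling a
unit-amplitude voxel with the protocol's own signal model and pushing it
through the same linear design the chosen fitter uses — so each route
(IDEAL, IDEAL-modes, linear) undoes exactly its own relaxation and
readout weighting. The deuteron bookkeeping treats the 10.12 mM reference
as deuteron-equivalent molarity of the water pool with `n_labels = 1`;
both the reference value and the label counts are configurable. ME maps
are shift-corrected by the exact inverse Fourier translation of the
simulator's chemical-shift displacement before ratioing. Voxels whose
water amplitude is below three noise SDs are masked rather than zeroed.

# PSF analysis

Acquisition weights are the separable 3-D Hamming product scaled to
`n_averages` and discretized round-half-up (floor is available behind a
flag), or uniform weights under an elliptical mask over the phase-encode
plane. Two resolution measures are reported: the per-axis full width of
the PSF at 64 % peak height — the level at which an unweighted sinc PSF
is exactly one nominal voxel wide — measured on the 32-fold zero-padded
transform of the axis marginals, and the PSF-integral effective voxel
volume `prod(FOV)·max(w)/Σw` (the volume of a box PSF with the same
peak-to-integral ratio). The integral volume is the figure quoted as "PSF
voxel volume" for the presets (≈4.2, 4.5 and 2.5 mL): it reduces to the
nominal voxel for uniform full sampling and accounts for the full 3-D
weighting including corners, which the FW64 product under-counts for
strongly apodized weightings.

# The synthetic scenes, and what the tests do not show

`build_scene()` emulates either a nine-vial spherical phantom (20 mL
vials on a peripheral ring) or an ellipsoidal brain with a smooth
second-order B₀ map spanning 210 Hz by default and smooth exterior-lobe
coil sensitivities with a correlated channel noise covariance. The
simulator forward-models the per-voxel steady state at each sample time
and phase cycle, adds a mono-exponential T2* envelope on top of the
steady-state amplitude (Lorentzian-equivalent static dephasing;
`t2star = FALSE` reproduces the fitters' own models exactly), applies the
per-metabolite read-axis displacement for ME encoding as a sub-voxel
Fourier shift, and realizes acquisition weighting as averaged
acquisitions with noise variance `1/w` (the acquisition count bookkeeping
is preserved for scan-time checks).

Module tests use grids of 8–24 voxels per axis and spectral sampling of
6–16 points — sizes chosen so the full suite runs in well under a minute
of simulation time while keeping every estimator in its asymptotic
regime. Quantitative round-trip checks use band-limited (edge-smoothed)
scenes and in-band B₀ spans: with sharp-edged objects at these coarse
grids, Gibbs ringing — a property of the acquisition, not of the code —
dominates the few-percent error budget; with B₀ excursions beyond one
banding period the bSSFP Δf₀ is fundamentally aliased and per-voxel
amplitude biases appear. Neither effect is hidden: both are demonstrated
by the sharp-edge and wide-span configurations of the same generators.
What the synthetic tests cannot show are scanner-level effects: actual
flip angles below nominal, transmit/receive inhomogeneity beyond smooth
lobes, frequency drifts, imperfect steady-state transitions between phase
cycles (dummy cycles are assumed perfect), physiological motion, and the
non-Lorentzian water lineshape.

# Known limitations

* Gradient waveforms, RF pulse shapes and electromagnetic SAR are out of
  scope; the SAR model is one calibrated scalar.
* The scan-time bookkeeping of the Hamming-weighted CSI presets
  (Σ weights × TR ≈ 15.5 min) exceeds their nominal 10-minute design
  slot; the preset parameters are kept as published and `scan_time_s()`
  reports the computed value. The ME preset fits its slot (≈8.4 min).
* The raw-data container is a versioned, checksummed RDS serialization
  with a lossless complex round-trip; maps export to NIfTI-1.
* Off-resonance estimation is per-voxel; no spatial regularization or
  region growing is applied.
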