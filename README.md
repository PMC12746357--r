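# pcdmi — phase-cycled balanced SSFP deuterium metabolic imaging

Deuterium metabolic imaging (DMI) maps the uptake and metabolism of
deuterated glucose in vivo from the sparse ²H spectrum (water 4.70 ppm,
glucose 3.80 ppm, Glx 2.35 ppm, lactate/lipid 1.37 ppm). Its intrinsically
low sensitivity makes the choice of steady-state sequence and of the
spectral-separation algorithm decisive. `pcdmi` implements, as a tested R
library, the computational machinery of a 9.4 T human DMI protocol family
built on phase-cycled balanced SSFP (bSSFP):

* **Signal models** — analytical FISP (SSFP-FID) and phase-cycled bSSFP
  steady states. The bSSFP signal of resonance *j* at time *t* after
  excitation, with per-TR phase `Φⱼ = 2π(Δfⱼ + Δf₀)TR` and
  `θⱼ = Φⱼ − ψ` for RF phase increment ψ, is

  ```
  S_j(t, ψ) = (1 − E₁) sin α (1 − E₂ e^{−iθⱼ})
              ───────────────────────────────────────────────  e^{−t/T₂} e^{i(t/TR)Φⱼ}
              (1 − E₁cos α)(1 − E₂cos θⱼ) − (E₁ − cos α)(E₂ − cos θⱼ)E₂
  ```

  with `E₁ = e^{−TR/T₁}`, `E₂ = e^{−TR/T₂}`. Signal efficiency
  (amplitude × matched-filter readout factor / √TR), phase-cycling SNR
  loss, SAR power bookkeeping and protocol comparison build on this.
* **Reconstruction in SNR units** — noise prewhitening, acquisition-
  weighted averaging with analytic noise tracking, zero-padded unitary
  FFT, adaptive (matched-filter) coil combination; background noise SD is
  exactly 1 in the output, so pixel values read as SNR.
* **Spectral separation** — three fitters: standard IDEAL
  (variable-projection joint estimation of complex amplitudes and the B₀
  off-resonance), **IDEAL-modes** (per-configuration-order IDEAL after a
  DFT along the phase-cycle axis, with data-driven principal-eigenvector
  combination of the mode amplitudes), and a **linear fit** against the
  full bSSFP signal model across all phase cycles. Conditioning and
  Fisher-information NSA diagnostics included.
* **Relaxometry** — combined spectral–temporal (Lorentzian × exponential)
  variable-projection fits of inversion-recovery and spin-echo series
  (T₁, T₂, bi-exponential ventricular water) and single-spectrum peak
  fits (T₂*, chemical shifts).
* **Quantification** — absolute mM maps against the 10.12 mM ²H-water
  reference, fitter-consistent relaxation calibration factors, 33 % Glx
  label-loss correction and sub-voxel chemical-shift displacement
  correction for the low-bandwidth multi-echo readout.
* **PSF / resolution analysis** — discretized Hamming acquisition
  weighting and elliptical scanning, per-axis PSF full width at 64 % peak
  height and the PSF-integral effective voxel volume.
* **Digital phantom** — a nine-vial sphere or ellipsoidal brain scene with
  smooth B₀ maps and coil sensitivities, simulated to multi-channel raw
  k-space for every protocol, so the entire chain is testable without a
  scanner.

The three shipped protocol presets (`csi`, `csi_pc_bssfp`, `me_pc_bssfp`)
and the in vivo / phantom relaxation tables mirror the acquisition
parameters of the study protocols at 9.4 T.

## Worked example

```r
library(pcdmi)
protos <- lapply(c("csi", "csi_pc_bssfp", "me_pc_bssfp"), dmi_protocol)
mets   <- dmi_metabolites("in_vivo")[c("water", "glucose", "glx")]
compare_protocols(protos, mets, reference = "csi")
#>   metabolite     protocol efficiency pct_change
#> 1      water          csi     0.1039        0.0
#> 2    glucose          csi     0.2053        0.0
#> 3        glx          csi     0.1893        0.0
#> 4      water csi_pc_bssfp     0.0895      -13.8
#> 5    glucose csi_pc_bssfp     0.3028       47.5
#> 6        glx csi_pc_bssfp     0.3091       63.3
#> 7      water  me_pc_bssfp     0.0859      -17.3
#> 8    glucose  me_pc_bssfp     0.2898       41.2
#> 9        glx  me_pc_bssfp     0.2951       55.9
```

The phase-cycled bSSFP CSI variant gains ~48 % SNR efficiency for glucose
and ~63 % for Glx over the vendor-style FISP-CSI reference (their short
T₂* penalizes the long FISP readout, while the balanced sequence retains
the T₂-refocused signal), at a small loss for water whose low T₂/T₁ ratio
does not favor bSSFP. Resolution and voxel-shift analysis:

```r
p <- dmi_protocol("me_pc_bssfp")
psf_metrics(acquisition_weights(p), p$fov_mm)
#> ME-PC-bSSFP: FW64 = 12.4 x 14.8 x 14.4 mm, PSF volume 2.54 mL (nominal 1.95 mL)
chemical_shift_displacement(dmi_metabolites("in_vivo")$glucose, p)
#> [1] 1.86   # mm along the read axis
```

A full synthetic pipeline run (scene → raw data → SNR-unit recon →
IDEAL-modes fit → mM maps) is two calls:

```r
cfg <- run_config("csi_pc_bssfp", "phantom", "ideal_modes", seed = 1,
                  grid = c(12, 12, 6))
cfg$protocol$matrix <- c(12L, 12L, 6L)
run_simulate(cfg)
fit <- run_fit(cfg)   # NIfTI maps + JSON report in cfg$out_dir
```

A thin command-line front-end with the same operations is installed at
`inst/cli/dmi` (`dmi simulate`, `dmi fit`, `dmi psf`,
`dmi compare-protocols`, `dmi sar`).

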