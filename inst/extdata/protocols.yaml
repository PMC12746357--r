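# Acquisition parameters of the three DMI protocols (10-min spectral-spatial
# 2H protocols at 9.4 T). readout_ms = TR * adc_duty for the CSI protocols;
# n_samples is the simulated spectral sampling of the CSI readout (the
# simulator's dwell time = readout_ms / n_samples).
csi:
  encoding: csi
  sequence: fisp
  TR_ms: 36.0
  flip_deg: 41.0
  rf_dur_ms: 0.5
  adc_duty: 0.79
  K_phase_cycles: 1
  n_averages: 12
  weighting: hamming
  mask: full
  fov_mm: [208, 208, 208]
  matrix: [25, 25, 25]
  readout_ms: 28.44
  n_samples: 32
csi_pc_bssfp:
  encoding: csi
  sequence: bssfp
  TR_ms: 19.0
  flip_deg: 50.0
  rf_dur_ms: 1.4
  adc_duty: 0.78
  K_phase_cycles: 4
  n_averages: 6
  weighting: hamming
  mask: full
  fov_mm: [208, 208, 208]
  matrix: [25, 25, 25]
  readout_ms: 14.82
  n_samples: 16
me_pc_bssfp:
  encoding: multi_echo
  sequence: bssfp
  TR_ms: 19.0
  flip_deg: 50.0
  rf_dur_ms: 1.4
  adc_duty: 0.71
  K_phase_cycles: 18
  n_averages: 5
  weighting: uniform
  mask: elliptical
  fov_mm: [400, 200, 300]
  matrix: [32, 16, 24]
  echo_spacing_ms: 3.4
  n_echoes: 5
  read_axis: 1
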