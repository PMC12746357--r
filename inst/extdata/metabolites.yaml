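# Relaxation times (ms) and chemical shifts (ppm) of the deuterium
# resonances at 9.4 T. "in_vivo" holds the brain values (n = 5); "phantom"
# the values measured in the multi-compound vial phantom. The in vivo water
# entry carries the ventricular long-T2 compartment seen in bi-exponential
# spin-echo fits.
in_vivo:
  water:
    shift_ppm: 4.70
    T1_ms: 371
    T2_ms: 30
    T2star_ms: 21
    n_labels: 1
    long_T2_ms: 293
    long_fraction: 0.18
  glucose:
    shift_ppm: 3.80
    T1_ms: 71
    T2_ms: 41
    T2star_ms: 14
    n_labels: 2
  glx:
    shift_ppm: 2.35
    T1_ms: 153
    T2_ms: 98
    T2star_ms: 23
    n_labels: 1
  lactate:
    shift_ppm: 1.37
    T1_ms: 139
    T2_ms: 138
    T2star_ms: 24
    n_labels: 3
phantom:
  water:
    shift_ppm: 4.70
    T1_ms: 488
    T2_ms: 275
    T2star_ms: 75
    n_labels: 1
  glucose:
    shift_ppm: 3.62
    T1_ms: 64
    T2_ms: 60
    T2star_ms: 22
    n_labels: 2
  glutamate:
    shift_ppm: 2.16
    T1_ms: 210
    T2_ms: 122
    T2star_ms: 53
    n_labels: 1
  lactate:
    shift_ppm: 1.18
    T1_ms: 266
    T2_ms: 258
    T2star_ms: 76
    n_labels: 3
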