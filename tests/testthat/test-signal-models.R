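nuc <- nucleus_field()
iv <- dmi_metabolites("in_vivo")

test_that("FISP steady state has the right limits and matches the Bloch oracle", {
  m <- metabolite_spec("w", 4.70, 371, 30, 21)
  expect_equal(fisp_steady_state(m, 36, 0), 0)
  # full recovery at TR >> T1 gives sin(alpha)
  expect_equal(fisp_steady_state(m, 1e6 * 371, pi / 2), 1, tolerance = 1e-6)
  expect_error(fisp_steady_state(metabolite_spec("b", 0, 100, 50, 20), -1, 1))
  # protocol operating point against the isochromat simulation
  expect_equal(fisp_steady_state(m, 36, 41 * pi / 180),
               bloch_fisp_oracle(371, 30, 36, 41 * pi / 180),
               tolerance = 1e-4)
  expect_equal(fisp_steady_state(iv$glucose, 36, 41 * pi / 180),
               bloch_fisp_oracle(71, 41, 36, 41 * pi / 180),
               tolerance = 1e-4)
})

test_that("bSSFP signal matches the period-steady-state Bloch oracle", {
  m <- iv$glucose
  df_j <- ppm_to_hz(nuc, m$shift_ppm)
  set.seed(7)
  for (i in 1:25) {
    T1 <- runif(1, 60, 500); T2 <- runif(1, 20, T1)
    TR <- runif(1, 10, 40); a <- runif(1, 0.2, 1.4)
    psi <- runif(1, 0, 2 * pi); df0 <- runif(1, -30, 30)
    tt <- runif(1, 0, TR)
    mm <- metabolite_spec("x", m$shift_ppm, T1, T2, min(T2, 15))
    got <- bssfp_signal(mm, steady_state_eval(a, psi, df0, tt), TR, nuc)
    want <- bloch_bssfp_oracle(T1, T2, TR, a, psi, df_j + df0, tt)
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("bSSFP passband exceeds stopband and zero flip gives zero", {
  m <- iv$water
  expect_equal(Mod(bssfp_signal(m, steady_state_eval(0, pi, 0, 0), 19, nuc)), 0)
  pass <- Mod(bssfp_signal(m, steady_state_eval(50 * pi / 180, pi, 0, 0), 19, nuc))
  stop_ <- Mod(bssfp_signal(m, steady_state_eval(50 * pi / 180, 0, 0, 0), 19, nuc))
  expect_gt(pass, stop_)
})

test_that("FISP amplitude lies between bSSFP stopband and passband levels", {
  for (m in dmi_metabolites("phantom")) {
    p <- dmi_protocol("csi_pc_bssfp")
    a <- p$flip_deg * pi / 180
    fisp <- fisp_steady_state(m, p$TR_ms, a)
    pass <- Mod(bssfp_signal(m, steady_state_eval(a, pi, -ppm_to_hz(nuc, m$shift_ppm), 0), p$TR_ms, nuc))
    stop_ <- Mod(bssfp_signal(m, steady_state_eval(a, 0, -ppm_to_hz(nuc, m$shift_ppm), 0), p$TR_ms, nuc))
    expect_gte(fisp, stop_)
    expect_lte(fisp, pass)
  }
})

test_that("frequency response is periodic in off-resonance and psi", {
  p <- small_protocol(n_samples = 5)
  m <- iv$glx
  psi <- c(pi, pi / 3)
  df <- c(-10, 0, 15)
  r0 <- frequency_response(m, p, psi, df, nuc)
  expect_equal(dim(r0), c(2, 3, 5))
  r_shift <- frequency_response(m, p, psi, df + 1000 / p$TR_ms, nuc)
  # magnitude is 1/TR-periodic; the complex value picks up the linear
  # phase ramp of the extra off-resonance
  expect_equal(Mod(r_shift), Mod(r0), tolerance = 1e-10)
  r_psi <- frequency_response(m, p, psi + 2 * pi, df, nuc)
  expect_equal(r_psi, r0, tolerance = 1e-10)
})

test_that("readout SNR factor has the no-decay and zero-length limits", {
  p <- small_protocol()
  m <- metabolite_spec("x", 3.8, 1e9, 1e8, 1e7)
  expect_equal(readout_snr_factor(m, p), sqrt(p$readout_ms), tolerance = 1e-4)
  p0 <- p; p0$readout_ms <- 0
  expect_error(readout_snr_factor(iv$glucose, p0))
  # the shipped CSI preset uses the SNR-optimal readout of about
  # 1.26 x T2* for the assumed 22 ms T2*
  pc <- dmi_protocol("csi")
  expect_equal(pc$readout_ms / 22, 1.26, tolerance = 0.04)
})

test_that("signal efficiency definitional properties hold", {
  p <- small_protocol("csi", n_samples = 8)
  m <- metabolite_spec("x", 3.8, 1e7, 1e6, 1e5)  # no relaxation on this scale
  e1 <- signal_efficiency(m, p, nuc)
  p2 <- p; p2$TR_ms <- 2 * p$TR_ms
  # with negligible relaxation and an unchanged readout window the
  # efficiency scales as 1/sqrt(TR)
  p2$readout_ms <- p$readout_ms
  e2 <- signal_efficiency(m, p2, nuc)
  expect_equal(e2 / e1, 1 / sqrt(2), tolerance = 0.02)
  # non-negative over the flip range
  for (a in seq(0, 180, by = 30)) {
    pp <- small_protocol(); pp$flip_deg <- a
    expect_gte(signal_efficiency(iv$water, pp, nuc), 0)
  }
  pbad <- small_protocol(); pbad$sequence <- "flash"
  expect_error(signal_efficiency(iv$water, pbad, nuc), "unknown sequence")
})

test_that("phase-cycled efficiency reduces to K = 1 and approaches the quadrature RMS", {
  p1 <- small_protocol(); p1$K_phase_cycles <- 1L
  m <- iv$glucose
  e1 <- phase_cycled_efficiency(m, p1, nuc, df0 = "centered")
  s <- bssfp_signal(m, steady_state_eval(p1$flip_deg * pi / 180, pi, 0, 0),
                    p1$TR_ms, nuc)
  expect_equal(e1, Mod(s) * readout_snr_factor(m, p1) / sqrt(p1$TR_ms),
               tolerance = 1e-12)
  # large K converges to the RMS of the frequency response over psi
  pK <- small_protocol(); pK$K_phase_cycles <- 96L
  eK <- phase_cycled_efficiency(m, pK, nuc, df0 = "centered")
  want <- quadrature_rms_amplitude(m, pK, nuc) *
    readout_snr_factor(m, pK) / sqrt(pK$TR_ms)
  expect_equal(eK, want, tolerance = 1e-3)
  p0 <- p1; p0$K_phase_cycles <- 0L
  expect_error(phase_cycled_efficiency(m, p0, nuc))
})

test_that("phase cycling costs SNR for a passband-centered metabolite", {
  m <- iv$water  # on-resonance: the single 180-degree cycle is passband
  p1 <- small_protocol(); p1$K_phase_cycles <- 1L
  p4 <- small_protocol()
  e1 <- phase_cycled_efficiency(m, p1, nuc, df0 = "centered")
  e4 <- phase_cycled_efficiency(m, p4, nuc, df0 = "centered")
  expect_lte(e4, e1)
  # the simulated loss is bounded by the printed worst case
  expect_lte(100 * (1 - e4 / e1), 27 + 5)
})

test_that("efficiencies are invariant under shifting the ppm reference", {
  m <- iv$glucose
  p <- small_protocol()
  nuc2 <- nucleus_field(ref_ppm = 3.10)
  m2 <- metabolite_spec(m$name, m$shift_ppm - 1.60, m$T1_ms, m$T2_ms,
                        m$T2star_ms, m$n_labels)
  expect_equal(signal_efficiency(m, p, nuc),
               signal_efficiency(m2, p, nuc2), tolerance = 1e-10)
})

test_that("SAR power model scales as expected and presets are feasible", {
  p <- small_protocol()
  s1 <- sar_time_avg_power(p)
  p2 <- p; p2$TR_ms <- p$TR_ms / 2
  expect_equal(sar_time_avg_power(p2)$power_W, 2 * s1$power_W)
  p0 <- p; p0$flip_deg <- 0
  expect_equal(sar_time_avg_power(p0)$power_W, 0)
  expect_true(sar_time_avg_power(p0)$feasible)
  for (nm in c("csi", "csi_pc_bssfp", "me_pc_bssfp"))
    expect_true(sar_time_avg_power(dmi_protocol(nm))$feasible)
})

test_that("protocol comparison table is complete and self-referenced at zero", {
  protos <- list(dmi_protocol("csi"), dmi_protocol("csi_pc_bssfp"))
  mets <- iv[c("water", "glucose")]
  tab <- compare_protocols(protos, mets, reference = "csi")
  expect_equal(nrow(tab), 4)
  self <- tab[tab$protocol == "csi", "pct_change"]
  expect_equal(self, c(0, 0), tolerance = 1e-12)
  expect_error(compare_protocols(protos, mets, reference = "nope"),
               "not in the protocol list")
})
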