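nuc <- nucleus_field()
iv <- dmi_metabolites("in_vivo")

test_that("phase-cycle DFT recovers constants, mode counts and known mixtures", {
  # constant across cycles: only c = 0 survives
  img <- array(rep(2 + 1i, 2 * 3 * 4), c(2, 1, 1, 3, 4))
  ms <- dft_phase_cycles(img)
  expect_equal(ms$orders, -1:1)
  expect_equal(as.vector(ms$F[, , , , 2]), rep(2 + 1i, 6), tolerance = 1e-12)
  expect_lt(max(Mod(ms$F[, , , , c(1, 3)])), 1e-12)
  # K = 18 retains 17 configuration orders
  img18 <- array(complex_noise(5 * 18), c(5, 1, 1, 1, 18))
  expect_equal(dim(dft_phase_cycles(img18)$F)[5], 17L)
  expect_equal(dft_phase_cycles(img18)$C, 8L)
  # synthetic three-mode signal is inverted exactly
  psi <- phase_cycle_schedule(4L)
  a <- c(0.3 - 0.2i, 1.5 + 0.4i, -0.7 + 0.1i)  # c = -1, 0, 1
  sig <- sapply(psi, function(p) sum(a * exp(-1i * (-1:1) * p)))
  ms3 <- dft_phase_cycles(array(sig, c(1, 1, 1, 1, 4)))
  expect_equal(as.vector(ms3$F), a, tolerance = 1e-12)
  expect_warning(dft_phase_cycles(array(0i, c(1, 1, 1, 1, 2))), "only the F0")
})

test_that("IDEAL recovers amplitudes and off-resonance from noiseless data", {
  p <- small_protocol("csi", n_samples = 24)
  basis <- metabolite_basis(iv, p, nuc)
  tn <- basis$t_ms
  # single metabolite at df0 = 0
  s1 <- 2.5 * exp(1i * 2 * pi * basis$shifts_Hz[2] * tn / 1000)
  f1 <- ideal_fit(matrix(s1, 1, byrow = TRUE), basis)
  expect_equal(Mod(f1$amplitudes[1, 2]), 2.5, tolerance = 1e-6)
  expect_equal(f1$df0_map_Hz[1], 0, tolerance = 1e-3)
  # four metabolites at df0 = 30 Hz
  amps <- c(3, 1.5, 0.8, 0.5) * exp(1i * c(0.3, -1, 2, 0.7))
  s4 <- colSums(amps * t(exp(1i * 2 * pi * outer(tn, basis$shifts_Hz + 30) / 1000)))
  f4 <- ideal_fit(matrix(s4, 1, byrow = TRUE), basis)
  expect_equal(f4$df0_map_Hz[1], 30, tolerance = 1e-3)
  expect_equal(as.vector(f4$amplitudes), amps, tolerance = 1e-6)
  expect_lt(f4$residual[1], 1e-9)
  # zero-signal voxel is flagged invalid, not NaN-propagated
  f0 <- ideal_fit(rbind(s4, 0), basis)
  expect_false(f0$valid[2])
  expect_true(all(is.na(f0$amplitudes[2, ])))
  expect_true(all(is.finite(f0$amplitudes[1, ]) | Mod(f0$amplitudes[1, ]) >= 0))
})

test_that("bSSFP off-resonance estimates wrap at the aliasing period", {
  p <- small_protocol(n_samples = 12)
  basis <- metabolite_basis(iv, p, nuc)
  tn <- basis$t_ms
  period <- 1000 / p$TR_ms
  s <- 2 * exp(1i * 2 * pi * (basis$shifts_Hz[1] + 5) * tn / 1000)
  f <- ideal_fit(matrix(s, 1, byrow = TRUE), basis)
  expect_equal(f$df0_map_Hz[1], 5, tolerance = 1e-2)
  expect_true(f$df0_map_Hz[1] > -period / 2 && f$df0_map_Hz[1] <= period / 2)
})

test_that("the F0 mode suppresses banding and yields a clean field map", {
  m <- dmi_metabolites("phantom")$water  # long T2: deep, narrow stopbands
  p <- small_protocol()
  a <- p$flip_deg * pi / 180
  psi <- phase_cycle_schedule(p)
  df_grid <- seq(-26, 26, length.out = 101)
  f0 <- vapply(df_grid, function(d)
    Mod(mean(bssfp_signal(m, steady_state_eval(a, psi, d, 0), p$TR_ms, nuc))),
    numeric(1))
  single <- vapply(df_grid, function(d)
    Mod(bssfp_signal(m, steady_state_eval(a, pi, d, 0), p$TR_ms, nuc)),
    numeric(1))
  cv <- function(x) stats::sd(x) / mean(x)
  expect_lt(cv(f0), 0.15)
  # the single 180-degree cycle shows strong banding in comparison
  expect_gt(cv(single), 0.2)
  expect_gt(cv(single), 10 * cv(f0))
  # noiseless constant off-resonance recovered within 0.5 Hz
  basis <- metabolite_basis(iv["water"], p, nuc)
  tn <- basis$t_ms
  sig <- vapply(psi, function(ps)
    bssfp_signal(m, steady_state_eval(a, ps, 9, tn), p$TR_ms, nuc),
    complex(length(tn)))
  img <- array(sig, c(1, 1, 1, length(tn), length(psi)))
  b0 <- estimate_b0_from_f0(img, basis, decay = "T2")
  expect_equal(b0$df0_map_Hz[1], 9, tolerance = 0.5)
})

test_that("IDEAL-modes inverts its own model exactly and orders mode power", {
  p <- small_protocol(n_samples = 10)
  basis <- metabolite_basis(iv, p, nuc)
  tn <- basis$t_ms; TRs <- p$TR_ms / 1000
  orders <- -1:1
  set.seed(5)
  P_true <- matrix(complex_noise(4 * 3), 4, 3)
  df0 <- 4
  FF <- array(0i, c(1, 1, 1, length(tn), 3))
  for (ci in 1:3) {
    Phi <- 2 * pi * (basis$shifts_Hz + df0) * TRs
    A <- exp(1i * 2 * pi / 1000 * outer(tn, basis$shifts_Hz + df0)) *
      rep(exp(1i * orders[ci] * Phi), each = length(tn))
    FF[1, 1, 1, , ci] <- A %*% P_true[, ci]
  }
  modes <- structure(list(F = FF, C = 1L, K = 4L, orders = orders),
                     class = "mode_set")
  mf <- ideal_modes_fit(modes, basis, df0)
  expect_equal(mf$P[1, , ], P_true, tolerance = 1e-10)
  # data from the full balanced steady-state model: mode power decays with |c|
  psi18 <- phase_cycle_schedule(18L)
  a <- p$flip_deg * pi / 180
  sig <- array(0i, c(1, 1, 1, length(tn), 18))
  for (k in 1:18) {
    s <- 0
    for (m in iv) s <- s + 2 * bssfp_signal(m, steady_state_eval(a, psi18[k], 0, tn),
                                            p$TR_ms, nuc)
    sig[1, 1, 1, , k] <- s
  }
  mf18 <- ideal_modes_fit(dft_phase_cycles(sig), basis, 0)
  for (j in 1:4) {
    pw <- Mod(mf18$P[1, j, ])
    i0 <- which(mf18$orders == 0)
    expect_true(all(pw[i0] >= pw[-i0]))
    # power falls off with configuration order
    expect_lt(stats::cor(pw, abs(mf18$orders), method = "spearman"), -0.8)
    expect_true(all(pw[abs(mf18$orders) >= 4] < 0.25 * pw[i0]))
  }
})

test_that("single-metabolite IDEAL-modes reduces to matched phase demodulation", {
  p <- small_protocol(n_samples = 6)
  basis1 <- metabolite_basis(iv["glucose"], p, nuc)
  tn <- basis1$t_ms
  FF <- array(0i, c(1, 1, 1, length(tn), 3))
  amp <- 1.3 - 0.6i
  for (ci in 1:3)
    FF[1, 1, 1, , ci] <- amp * exp(1i * 2 * pi * basis1$shifts_Hz * tn / 1000) *
      exp(1i * (ci - 2) * 2 * pi * basis1$shifts_Hz * p$TR_ms / 1000)
  modes <- structure(list(F = FF, C = 1L, K = 4L, orders = -1:1),
                     class = "mode_set")
  mf <- ideal_modes_fit(modes, basis1, 0)
  expect_equal(as.vector(mf$P[1, 1, ]), rep(amp, 3), tolerance = 1e-10)
})

test_that("principal-eigenvector combination handles the F0-only and generic cases", {
  # only F0 nonzero: weights reduce to the F0 indicator
  nvx <- 50
  set.seed(8)
  P <- array(0i, c(nvx, 1, 5))
  P[, 1, 3] <- 4 + complex_noise(nvx)
  mfit <- list(P = P, orders = -2:2, cond = rep(1, 5),
               mode_ok = rep(TRUE, 5),
               noise_scale = matrix(1, 1, 5), metabolites = "water", K = 12L)
  cm <- combine_modes_principal(mfit)
  expect_equal(Mod(cm$weights[3, 1]), 1, tolerance = 1e-9)
  expect_equal(cm$amplitudes[, 1], P[, 1, 3], tolerance = 1e-8)
  # weights track a known rank-one mode-decay profile
  prof <- c(0.1, 0.5, 1, 0.5, 0.1)
  P2 <- array(0i, c(nvx, 1, 5))
  base <- 5 + complex_noise(nvx) * 0.01
  for (ci in 1:5) P2[, 1, ci] <- base * prof[ci]
  mfit$P <- P2
  cm2 <- combine_modes_principal(mfit)
  w <- Mod(cm2$weights[, 1])
  expect_gt(abs(stats::cor(w, prof)), 0.9)
})

test_that("the linear bSSFP fit inverts its own model and flags conditioning", {
  p <- small_protocol(n_samples = 6)
  basis <- metabolite_basis(iv, p, nuc)
  psi <- phase_cycle_schedule(p)
  tn <- basis$t_ms
  amps <- c(4, 2, 1, 0.6) * exp(1i * c(0, 1, -2, 0.5))
  sig <- array(0i, c(1, 1, 1, length(tn), length(psi)))
  for (k in seq_along(psi)) {
    s <- 0
    for (j in 1:4) s <- s + amps[j] *
        bssfp_signal(iv[[j]], steady_state_eval(p$flip_deg * pi / 180,
                                                psi[k], 11, tn), p$TR_ms, nuc)
    sig[1, 1, 1, , k] <- s
  }
  lf <- linear_fit(sig, basis, 11)
  expect_equal(as.vector(lf$amplitudes), amps, tolerance = 1e-9)
  expect_true(all(lf$valid))
})

test_that("spectral separability needs phase cycles when echoes are few", {
  # 3 echoes, 4 metabolites: singular without phase cycling
  p <- dmi_protocol("me_pc_bssfp")
  p$n_echoes <- 3L
  tn <- sample_times_ms(p)
  shifts <- vapply(iv, function(m) ppm_to_hz(nuc, m$shift_ppm), numeric(1))
  A1 <- exp(1i * 2 * pi / 1000 * outer(tn, shifts))
  expect_gt(condition_number(A1), 1e10)
  expect_equal(nsa(A1), rep(0, 4))
  # the same three echoes with 18 phase cycles separate all four
  psi <- phase_cycle_schedule(18L)
  cols <- sapply(seq_len(4), function(j)
    as.vector(outer(seq_along(tn), seq_len(18), function(n, k)
      bssfp_signal(iv[[j]], steady_state_eval(p$flip_deg * pi / 180, psi[k],
                                              0, tn[n]),
                   p$TR_ms, nuc))))
  expect_lt(condition_number(cols), 1e4)
})

test_that("condition numbers improve (non-strictly) with more phase cycles", {
  p <- dmi_protocol("me_pc_bssfp")
  basis <- metabolite_basis(iv, p, nuc)
  set.seed(12)
  df0s <- runif(12, -25, 25)
  meancond <- vapply(c(4, 8, 18), function(K) {
    psi <- phase_cycle_schedule(as.integer(K))
    mean(vapply(df0s, function(d) {
      cols <- sapply(seq_len(4), function(j)
        as.vector(outer(seq_along(basis$t_ms), seq_len(K), function(n, k)
          bssfp_signal(iv[[j]], steady_state_eval(p$flip_deg * pi / 180,
                                                  psi[k], d, basis$t_ms[n]),
                       p$TR_ms, nuc))))
      condition_number(cols)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meancond) <= 1e-9))
})

test_that("condition number and NSA have their closed-form anchors", {
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))
  expect_equal(condition_number(Q), 1, tolerance = 1e-10)
  # orthogonal unit-modulus columns: NSA equals the number of samples
  N <- 8
  A <- exp(1i * 2 * pi * outer(0:(N - 1), c(0, 1, 2)) / N)
  expect_equal(nsa(A), rep(N, 3), tolerance = 1e-10)
  # identical shifts: collinear columns, NSA 0
  A2 <- cbind(A[, 1], A[, 1])
  expect_equal(nsa(A2), c(0, 0))
  # the ME preset echo spacing sits near the NSA optimum of the in vivo basis
  pme <- dmi_protocol("me_pc_bssfp")
  spacing <- seq(1, 6, by = 0.1)
  vals <- vapply(spacing, function(s) {
    pp <- pme; pp$echo_spacing_ms <- s
    b <- metabolite_basis(iv, pp, nuc)
    min(nsa(exp(1i * 2 * pi / 1000 * outer(b$t_ms, b$shifts_Hz))))
  }, numeric(1))
  at_proto <- vals[which.min(abs(spacing - pme$echo_spacing_ms))]
  expect_gt(at_proto / max(vals), 0.90)
})

test_that("SNR-unit scaling makes fitted map noise SD one and is idempotent", {
  p <- small_protocol("csi", n_samples = 16)
  basis <- metabolite_basis(iv, p, nuc)
  set.seed(3)
  nv <- 3000
  noise <- matrix(complex_noise(nv * 16), nv)
  f <- ideal_fit(noise, basis, df0_fixed = 0)
  sc <- scale_to_snr(f)
  for (j in 1:4)
    expect_equal(stats::sd(c(Re(sc$amplitudes[, j]), Im(sc$amplitudes[, j]))) *
                   sqrt(2), 1, tolerance = 0.04)
  expect_identical(scale_to_snr(sc)$amplitudes, sc$amplitudes)
  bad <- f; bad$snr_scale <- rep(0, 4)
  expect_error(scale_to_snr(bad), "snr_scale")
})

test_that("noiseless fitter round trips hold across generator models", {
  mets <- dmi_metabolites("phantom")
  p <- small_protocol(matrix = c(12, 12, 6), n_samples = 8)
  conc <- matrix(c(10, 3, 2, 1.5), 1, 4, dimnames = list(NULL, names(mets)))
  scene <- build_scene("ellipsoid_brain", mets, grid = c(12, 12, 6),
                       fov_mm = p$fov_mm, n_channels = 3, b0_span_Hz = 40,
                       conc_mM = conc, edge_smooth_vox = 1, seed = 2)
  raw <- simulate_acquisition(scene, p, seed = 3, noise = FALSE,
                              t2star = FALSE)
  img <- adaptive_combine(reconstruct(prewhiten(raw)))$img
  img <- img[seq(1, 23, 2), seq(1, 23, 2), seq(1, 11, 2), , , drop = FALSE]
  basis <- metabolite_basis(mets, p, nuc)
  b0 <- estimate_b0_from_f0(img, basis, decay = "T2")
  d <- dim(img)
  g <- expand.grid(x = 1:d[1], y = 1:d[2], z = 1:d[3])
  ctr <- d[1:3] %/% 2 + 1
  semi <- 0.42 * d[1:3] * 0.55
  inside <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2 <= 1
  # the full-model linear fit sees its own generator: interior amplitude
  # ratios match the scene
  lf <- linear_fit(img, basis, b0$df0_map_Hz)
  rat <- function(maps) {
    a <- apply(Mod(maps$amplitudes[inside, ]), 2, stats::median)
    a / a[1]
  }
  truth <- c(10, 6, 2, 4.5) / 10   # conc x n_labels, relative to water
  cal_l <- vapply(mets, function(m)
    calibration_factor(m, p, nuc, mets$water, "linear", t2star = FALSE),
    numeric(1))
  expect_equal(rat(lf) / cal_l, truth, tolerance = 0.05, ignore_attr = TRUE)
  # IDEAL-modes neglects T2 decay: documented small bias on full-model data
  mf <- combine_modes_principal(ideal_modes_fit(dft_phase_cycles(img),
                                                basis, b0$df0_map_Hz))
  cal_m <- vapply(mets, function(m)
    calibration_factor(m, p, nuc, mets$water, "ideal_modes", t2star = FALSE),
    numeric(1))
  expect_equal(rat(mf) / cal_m, truth, tolerance = 0.05, ignore_attr = TRUE)
})
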