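# Independent Bloch-simulation oracles: explicit per-TR rotation matrices
# iterated to steady state, with the RF phase incremented by psi each TR
# and the receiver demodulated by the same phase. The package's analytic
# expressions are checked against these (factor 1i aligns the excitation
# phase convention: rotation about x maps Mz to -y).

rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

bloch_bssfp_oracle <- function(T1, T2, TR, alpha, psi, df_Hz, t_ms,
                               n_tr = 4000) {
  E1 <- exp(-TR / T1); E2 <- exp(-TR / T2)
  beta <- 2 * pi * df_Hz * TR / 1000
  M <- c(0, 0, 1)
  phi <- 0
  for (n in seq_len(n_tr)) {
    phi <- phi + psi
    M <- rot_z(phi) %*% rot_x(alpha) %*% rot_z(-phi) %*% M
    if (n == n_tr) break
    Mxy <- complex(real = M[1], imaginary = M[2]) * exp(1i * beta) * E2
    M <- c(Re(Mxy), Im(Mxy), 1 - (1 - M[3]) * E1)
  }
  1i * complex(real = M[1], imaginary = M[2]) *
    exp(1i * 2 * pi * df_Hz * t_ms / 1000) * exp(-t_ms / T2) * exp(-1i * phi)
}

# FISP / SSFP-FID: no phase cycling, ideal spoiler gradient modeled as a
# uniform intravoxel dephasing of 2 pi per TR; voxel signal is the complex
# isochromat average directly after excitation.
bloch_fisp_oracle <- function(T1, T2, TR, alpha, n_iso = 360, n_tr = 3000) {
  E1 <- exp(-TR / T1); E2 <- exp(-TR / T2)
  betas <- 2 * pi * (seq_len(n_iso) - 0.5) / n_iso
  R <- rot_x(alpha)
  M <- matrix(rep(c(0, 0, 1), n_iso), 3)
  for (n in seq_len(n_tr)) {
    M <- R %*% M
    if (n == n_tr) break
    Mxy <- complex(real = M[1, ], imaginary = M[2, ]) * exp(1i * betas) * E2
    M <- rbind(Re(Mxy), Im(Mxy), 1 - (1 - M[3, ]) * E1)
  }
  Mod(mean(complex(real = M[1, ], imaginary = M[2, ])))
}

# brute-force quadrature of the phase-cycled RMS amplitude over a dense
# off-resonance grid (independent of the package's implementation path)
quadrature_rms_amplitude <- function(metabolite, protocol, nucleus,
                                     n_psi = 720) {
  alpha <- protocol$flip_deg * pi / 180
  df_j <- ppm_to_hz(nucleus, metabolite$shift_ppm)
  E1 <- exp(-protocol$TR_ms / metabolite$T1_ms)
  E2 <- exp(-protocol$TR_ms / metabolite$T2_ms)
  th <- 2 * pi * (seq_len(n_psi) - 0.5) / n_psi
  s <- (1 - E1) * sin(alpha) * (1 - E2 * exp(-1i * th)) /
    ((1 - E1 * cos(alpha)) * (1 - E2 * cos(th)) -
       (E1 - cos(alpha)) * (E2 - cos(th)) * E2)
  sqrt(mean(Mod(s)^2))
}

# small helpers shared by pipeline tests
complex_noise <- function(n) complex(real = stats::rnorm(n, sd = sqrt(0.5)),
                                     imaginary = stats::rnorm(n, sd = sqrt(0.5)))

small_protocol <- function(name = "csi_pc_bssfp", matrix = c(12, 12, 6),
                           n_samples = 8L) {
  p <- dmi_protocol(name)
  p$matrix <- as.integer(matrix)
  if (p$encoding == "csi") p$n_samples <- as.integer(n_samples)
  p
}
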