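#' Build a digital phantom or brain scene
#'
#' Constructs the ground truth for the simulator: per-metabolite
#' concentration and signal-amplitude maps (amplitude proportional to
#' concentration times deuteron count), a smooth B0 off-resonance map,
#' complex coil sensitivities and the channel noise covariance.
#'
#' The `"vials"` layout mimics a spherical multi-compound phantom: nine
#' spherical vials on a ring along the outer periphery of an 18 cm sphere,
#' each holding water plus one dominant deuterated compound. The
#' `"ellipsoid_brain"` layout is a three-axis ellipsoid with a smooth
#' second-order-polynomial B0 map spanning `b0_span_Hz` plus an optional
#' frontal gradient.
#'
#' @param layout `"vials"` or `"ellipsoid_brain"`.
#' @param metabolites named list of [metabolite_spec()]s.
#' @param grid 3-vector of voxels; should match the protocol matrix that
#'   will be simulated.
#' @param fov_mm 3-vector field of view in mm.
#' @param n_channels number of receive channels (8-10 typical).
#' @param b0_span_Hz peak-to-peak span of the B0 map (default 210 Hz, i.e.
#'   3.5 ppm at the 2H frequency at 9.4 T).
#' @param frontal_gradient_Hz extra linear gradient along +y for the brain
#'   layout.
#' @param noise_corr off-diagonal channel noise correlation.
#' @param conc_mM optional matrix `[vial, metabolite]` of concentrations;
#'   defaults to 10 mM water everywhere plus 8 mM of one dominant compound
#'   cycling through the non-water metabolites.
#' @param edge_smooth_vox Gaussian smoothing (SD in voxels) applied to the
#'   concentration maps; use > 0 for band-limited objects whose interior
#'   is free of Gibbs ringing at the acquisition resolution.
#' @param seed RNG seed for reproducible sensitivity phases.
#' @return object of class `phantom_scene`.
#' @export
build_scene <- function(layout = c("vials", "ellipsoid_brain"),
                        metabolites = dmi_metabolites("phantom"),
                        grid = c(24, 24, 24),
                        fov_mm = c(208, 208, 208),
                        n_channels = 8,
                        b0_span_Hz = 210,
                        frontal_gradient_Hz = 0,
                        noise_corr = 0.2,
                        conc_mM = NULL,
                        edge_smooth_vox = 0,
                        seed = 1L) {
  layout <- match.arg(layout)
  set.seed(seed)
  M <- length(metabolites)
  ax <- lapply(1:3, function(a)
    (seq_len(grid[a]) - (grid[a] %/% 2 + 1)) * fov_mm[a] / grid[a])
  X <- array(rep(ax[[1]], times = prod(grid[2:3])), grid)
  Y <- aperm(array(rep(ax[[2]], times = grid[1] * grid[3]),
                   c(grid[2], grid[1], grid[3])), c(2, 1, 3))
  Z <- aperm(array(rep(ax[[3]], times = prod(grid[1:2])),
                   c(grid[3], grid[1], grid[2])), c(2, 3, 1))
  conc <- array(0, c(grid, M), dimnames = list(NULL, NULL, NULL,
                                               names(metabolites)))
  if (layout == "vials") {
    n_vials <- 9L
    ring_r <- 0.29 * fov_mm[1]
    vial_r <- 16.8  # 20 mL sphere
    if (is.null(conc_mM)) {
      conc_mM <- matrix(0, n_vials, M, dimnames = list(NULL,
                                                       names(metabolites)))
      iw <- match("water", names(metabolites))
      others <- setdiff(seq_len(M), iw)
      for (v in seq_len(n_vials)) {
        if (!is.na(iw)) conc_mM[v, iw] <- 10
        if (length(others))
          conc_mM[v, others[(v - 1) %% length(others) + 1]] <- 8
      }
    }
    ang <- 2 * pi * (seq_len(n_vials) - 1) / n_vials
    ctrs <- cbind(ring_r * cos(ang), ring_r * sin(ang), 0)
    dmin <- min(stats::dist(ctrs))
    if (dmin < 2 * vial_r) stop("vials overlap: ring too small for radius")
    mask <- array(FALSE, grid)
    for (v in seq_len(n_vials)) {
      inside <- (X - ctrs[v, 1])^2 + (Y - ctrs[v, 2])^2 +
        (Z - ctrs[v, 3])^2 <= vial_r^2
      mask <- mask | inside
      for (j in seq_len(M)) conc[, , , j][inside] <- conc_mM[v, j]
    }
    b0 <- b0_span_Hz * ((X^2 + Y^2 - 2 * Z^2) /
                          max(abs(X^2 + Y^2 - 2 * Z^2)) / 2)
  } else {
    semi <- 0.42 * fov_mm
    inside <- (X / semi[1])^2 + (Y / semi[2])^2 + (Z / semi[3])^2 <= 1
    mask <- inside
    if (is.null(conc_mM)) {
      conc_mM <- matrix(c(10, rep(2, M - 1)), 1, M,
                        dimnames = list(NULL, names(metabolites)))
    }
    for (j in seq_len(M)) conc[, , , j][inside] <- conc_mM[1, j]
    quad <- (X / semi[1])^2 + (Y / semi[2])^2 - 2 * (Z / semi[3])^2
    b0 <- b0_span_Hz * (quad - min(quad)) / diff(range(quad)) -
      b0_span_Hz / 2 + frontal_gradient_Hz * (Y / semi[2])
  }
  if (edge_smooth_vox > 0) {
    gk <- function(N) {
      x <- c(0:(N %/% 2), -((N - N %/% 2 - 1):1))
      g <- exp(-x^2 / (2 * edge_smooth_vox^2))
      g / sum(g)
    }
    Kf <- stats::fft(gk(grid[1])) %o% stats::fft(gk(grid[2])) %o%
      stats::fft(gk(grid[3]))
    for (j in seq_len(M))
      conc[, , , j] <- Re(stats::fft(stats::fft(conc[, , , j]) * Kf,
                                     inverse = TRUE)) / prod(grid)
  }
  amp <- conc
  for (j in seq_len(M)) amp[, , , j] <- conc[, , , j] * metabolites[[j]]$n_labels
  # smooth exterior-lobe coil sensitivities on a ring around the object
  sens <- array(0i, c(grid, n_channels))
  coil_r <- 0.62 * max(fov_mm)
  width <- 0.55 * max(fov_mm)
  for (ch in seq_len(n_channels)) {
    a <- 2 * pi * (ch - 1) / n_channels
    cx <- coil_r * cos(a); cy <- coil_r * sin(a)
    d2 <- (X - cx)^2 + (Y - cy)^2 + Z^2
    ph <- stats::runif(1, -pi, pi) + 0.002 * (X * cos(a) + Y * sin(a))
    sens[, , , ch] <- exp(-d2 / (2 * width^2)) * exp(1i * ph)
  }
  ncov <- (1 - noise_corr) * diag(n_channels) +
    noise_corr * outer(0.9^(seq_len(n_channels)),
                       0.9^(seq_len(n_channels)))
  ncov <- ncov / mean(diag(ncov))
  structure(list(layout = layout, metabolites = metabolites,
                 grid = as.integer(grid), fov_mm = fov_mm,
                 conc_maps_mM = conc, amplitude_maps = amp,
                 b0_map_Hz = b0, coil_sens = sens, noise_cov = ncov,
                 mask = mask, seed = seed),
            class = "phantom_scene")
}

#' Simulate a raw acquisition from a scene
#'
#' Forward-models the voxel-wise steady-state signal of every metabolite
#' at the protocol's sample times and phase cycles (analytical FISP for
#' FISP protocols; the balanced steady-state model at the voxel's
#' off-resonance and each RF phase increment for bSSFP protocols), applies
#' a per-metabolite mono-exponential T2* envelope on top of the
#' steady-state amplitude when `t2star = TRUE`, encodes each channel to
#' k-space with the coil sensitivities, realizes the acquisition weighting
#' as averaged repeated acquisitions (per-point noise variance `1 / w`)
#' and adds complex Gaussian channel noise with the scene covariance.
#' Multi-echo protocols displace each metabolite along the frequency-encode
#' axis by its chemical-shift pixel shift (monopolar readout, see
#' [chemical_shift_displacement()]).
#'
#' @param scene a [build_scene()] result; its grid must match the protocol
#'   matrix.
#' @param protocol a [protocol_spec()].
#' @param seed RNG seed for the noise.
#' @param nucleus a [nucleus_field()].
#' @param noise logical; set `FALSE` for a noiseless acquisition.
#' @param t2star include the T2* envelope (replaces the model's T2 decay
#'   with the faster T2* decay for balanced sequences).
#' @param amp_scale global multiplier on the scene amplitudes; with unit
#'   per-acquisition noise this sets the simulated SNR.
#' @param n_noise number of noise-only samples per channel.
#' @return a [dmi_raw()].
#' @export
simulate_acquisition <- function(scene, protocol, seed = 1L,
                                 nucleus = nucleus_field(),
                                 noise = TRUE, t2star = TRUE,
                                 amp_scale = 1, n_noise = 2048L) {
  if (!all(scene$grid == protocol$matrix))
    stop("scene grid (", paste(scene$grid, collapse = "x"),
         ") does not match protocol matrix (",
         paste(protocol$matrix, collapse = "x"), ")")
  set.seed(seed)
  mets <- scene$metabolites
  M <- length(mets)
  tn <- sample_times_ms(protocol)
  psi <- phase_cycle_schedule(protocol)
  ns <- length(tn); K <- length(psi)
  nc <- dim(scene$coil_sens)[4]
  mat <- scene$grid
  alpha <- protocol$flip_deg * pi / 180
  w <- acquisition_weights(protocol)$weights
  df0 <- scene$b0_map_Hz
  # steady-state complex factor per voxel, metabolite, cycle (t = 0)
  ss <- array(0i, c(prod(mat), M, K))
  for (j in seq_len(M)) {
    m <- mets[[j]]
    if (protocol$sequence == "fisp") {
      ss[, j, ] <- fisp_steady_state(m, protocol$TR_ms, alpha)
    } else {
      df_j <- ppm_to_hz(nucleus, m$shift_ppm)
      E1 <- exp(-protocol$TR_ms / m$T1_ms)
      E2 <- exp(-protocol$TR_ms / m$T2_ms)
      Phi <- 2 * pi * (df_j + as.vector(df0)) * protocol$TR_ms / 1000
      for (k in seq_len(K)) {
        th <- Phi - psi[k]
        num <- (1 - E1) * sin(alpha) * (1 - E2 * exp(-1i * th))
        den <- (1 - E1 * cos(alpha)) * (1 - E2 * cos(th)) -
          (E1 - cos(alpha)) * (E2 - cos(th)) * E2
        ss[, j, k] <- num / den
      }
    }
  }
  # temporal decay + phase evolution per metabolite
  decay <- matrix(0i, ns, M)
  phase_vox <- array(0i, c(prod(mat), ns, M))
  for (j in seq_len(M)) {
    m <- mets[[j]]
    tau <- if (protocol$sequence == "fisp") m$T2star_ms
           else if (t2star) m$T2star_ms else m$T2_ms
    decay[, j] <- exp(-tn / tau)
    df_j <- ppm_to_hz(nucleus, m$shift_ppm)
    phase_vox[, , j] <- exp(1i * 2 * pi / 1000 *
                              outer(df_j + as.vector(df0), tn))
  }
  # per-metabolite chemical-shift displacement along the read axis
  ramp <- vector("list", M)
  if (protocol$encoding == "multi_echo") {
    ra <- protocol$read_axis
    kidx <- seq_len(mat[ra]) - (mat[ra] %/% 2 + 1)
    for (j in seq_len(M)) {
      sh_mm <- chemical_shift_displacement(mets[[j]], protocol, nucleus)
      sh_vox <- sh_mm / (protocol$fov_mm[ra] / mat[ra])
      r1 <- exp(-1i * 2 * pi * kidx * sh_vox / mat[ra])
      full <- array(0i, mat)
      perm <- c(ra, setdiff(1:3, ra))
      tmp <- array(rep(r1, times = prod(mat[-ra])), c(mat[ra], mat[-ra]))
      ramp[[j]] <- aperm(tmp, order(perm))
    }
  }
  Lc <- chol_complex(scene$noise_cov)
  sdk <- 1 / sqrt(pmax(as.vector(w), 1))
  sdk[as.vector(w) == 0] <- 0
  data <- array(0i, c(nc, mat, ns, K))
  for (s in seq_len(ns)) for (k in seq_len(K)) {
    nz <- if (noise) Lc %*% matrix(rcnorm(nc * prod(mat)), nc) else NULL
    for (ch in seq_len(nc)) {
      ksp <- array(0i, mat)
      for (j in seq_len(M)) {
        vol <- array(amp_scale * as.vector(scene$amplitude_maps[, , , j]) *
                       ss[, j, k] * phase_vox[, s, j] * decay[s, j], mat)
        kj <- img_to_kspace(vol * scene$coil_sens[, , , ch]) * sqrt(prod(mat))
        if (!is.null(ramp[[j]])) kj <- kj * ramp[[j]]
        ksp <- ksp + kj
      }
      if (noise) ksp <- ksp + array(nz[ch, ] * sdk, mat)
      ksp[array(as.vector(w) == 0, mat)] <- 0i
      data[ch, , , , s, k] <- ksp
    }
  }
  noise_samp <- Lc %*% matrix(rcnorm(nc * n_noise), nc)
  dmi_raw(data, noise_samp, w, protocol, nucleus, seed = seed)
}
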