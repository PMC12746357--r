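#' Quantification configuration
#'
#' @param water_ref_mM assumed homogeneous deuterated-water reference
#'   concentration (default 10.12 mM).
#' @param glx_label_loss fraction of deuterium labels lost in the
#'   glucose-to-Glx transformation during oxidative metabolism (0.33).
#' @param reference_volume index of the water volume used as reference
#'   (the earliest-time-point water image).
#' @return object of class `quant_config`.
#' @export
quant_config <- function(water_ref_mM = 10.12, glx_label_loss = 0.33,
                         reference_volume = 1L) {
  stopifnot(water_ref_mM > 0, glx_label_loss >= 0, glx_label_loss < 1)
  structure(list(water_ref_mM = water_ref_mM,
                 glx_label_loss = glx_label_loss,
                 reference_volume = as.integer(reference_volume)),
            class = "quant_config")
}

#' Chemical-shift voxel displacement of a multi-echo readout
#'
#' With the system frequency on water, a resonance offset by `df` Hz is
#' displaced along the frequency-encode axis by `df * T_adc` voxels,
#' where `T_adc = TR * adc_duty / n_echoes` is the per-echo ADC duration
#' (the reciprocal of the per-voxel bandwidth). Monopolar readout
#' gradients make the shift unidirectional. CSI protocols have no
#' frequency encoding and return 0.
#'
#' @param metabolite a [metabolite_spec()].
#' @param protocol a [protocol_spec()].
#' @param nucleus a [nucleus_field()].
#' @return displacement in mm along the read axis (positive for upfield
#'   resonances).
#' @export
chemical_shift_displacement <- function(metabolite, protocol,
                                        nucleus = nucleus_field()) {
  if (protocol$encoding == "csi") {
    message("csi protocol: no frequency encoding, displacement is 0")
    return(0)
  }
  df <- ppm_to_hz(nucleus, metabolite$shift_ppm)
  t_adc_s <- protocol$TR_ms * protocol$adc_duty / protocol$n_echoes / 1000
  vox_mm <- protocol$fov_mm[protocol$read_axis] /
    protocol$matrix[protocol$read_axis]
  -df * t_adc_s * vox_mm
}

#' Sub-voxel shift correction along the read axis
#'
#' Translates a volume by `-shift_mm` along the read axis with a Fourier
#' phase ramp (the exact inverse of the simulator's chemical-shift
#' displacement).
#'
#' @param vol 3-D numeric or complex array.
#' @param shift_mm displacement to undo, mm.
#' @param read_axis axis index (1..3).
#' @param voxel_mm voxel size along the read axis, mm.
#' @return corrected array (complex).
#' @export
apply_shift_correction <- function(vol, shift_mm, read_axis, voxel_mm) {
  if (shift_mm == 0) return(vol)
  d <- dim(vol)
  N <- d[read_axis]
  kidx <- seq_len(N) - (N %/% 2 + 1)
  ramp1 <- exp(1i * 2 * pi * kidx * (shift_mm / voxel_mm) / N)
  perm <- c(read_axis, setdiff(1:3, read_axis))
  ramp <- aperm(array(rep(ramp1, times = prod(d[-read_axis])),
                      c(N, d[-read_axis])), order(perm))
  kspace_to_img(img_to_kspace(vol) * ramp)
}

#' Temporal signal of a unit-amplitude voxel
#'
#' Forward-models the signal of one metabolite with unit amplitude at a
#' given off-resonance over the protocol's sample times and phase cycles -
#' the same voxel model the simulator uses (steady-state amplitude, T2*
#' envelope, phase evolution).
#'
#' @param metabolite a [metabolite_spec()].
#' @param protocol a [protocol_spec()].
#' @param df0_Hz off-resonance of the voxel.
#' @param nucleus a [nucleus_field()].
#' @param t2star apply the T2* envelope (simulator default).
#' @return complex matrix `[t, K]`.
#' @export
unit_voxel_signal <- function(metabolite, protocol, df0_Hz = 0,
                              nucleus = nucleus_field(), t2star = TRUE) {
  tn <- sample_times_ms(protocol)
  psi <- phase_cycle_schedule(protocol)
  alpha <- protocol$flip_deg * pi / 180
  df_j <- ppm_to_hz(nucleus, metabolite$shift_ppm)
  if (protocol$sequence == "fisp") {
    ss <- rep(fisp_steady_state(metabolite, protocol$TR_ms, alpha),
              length(psi))
  } else {
    E1 <- exp(-protocol$TR_ms / metabolite$T1_ms)
    E2 <- exp(-protocol$TR_ms / metabolite$T2_ms)
    th <- 2 * pi * (df_j + df0_Hz) * protocol$TR_ms / 1000 - psi
    ss <- (1 - E1) * sin(alpha) * (1 - E2 * exp(-1i * th)) /
      ((1 - E1 * cos(alpha)) * (1 - E2 * cos(th)) -
         (E1 - cos(alpha)) * (E2 - cos(th)) * E2)
  }
  tau <- if (protocol$sequence == "fisp" || t2star) metabolite$T2star_ms
         else metabolite$T2_ms
  env <- exp(-tn / tau) * exp(1i * 2 * pi * (df_j + df0_Hz) * tn / 1000)
  outer(env, ss)
}

#' Relaxation-weighting calibration factor
#'
#' The amplitude that the chosen spectral fitter reports for a
#' unit-amplitude voxel of the metabolite, relative to the same quantity
#' for water: forward-model the unit voxel with the protocol's signal
#' model and push it through the fitter's linear design (complex-averaged
#' IDEAL projection, root-sum-of-squares mode profile for IDEAL-modes, or
#' the full bSSFP-model projection for the linear fit). Dividing fitted
#' amplitude ratios by this factor undoes the sequence's relaxation and
#' readout weighting.
#'
#' @param metabolite a [metabolite_spec()].
#' @param protocol a [protocol_spec()].
#' @param nucleus a [nucleus_field()].
#' @param water reference [metabolite_spec()] (same table as the
#'   metabolite).
#' @param fitter which fitting route the maps came from.
#' @param t2star whether the acquisition model includes the T2* envelope.
#' @return unitless factor (1 for a metabolite with water's relaxation
#'   times and chemical shift).
#' @export
calibration_factor <- function(metabolite, protocol,
                               nucleus = nucleus_field(),
                               water,
                               fitter = c("ideal", "ideal_modes", "linear"),
                               t2star = TRUE) {
  fitter <- match.arg(fitter)
  if (is.null(metabolite$T1_ms) || is.null(water$T1_ms))
    stop("relaxation times missing for calibration")
  one <- function(m) {
    S <- unit_voxel_signal(m, protocol, 0, nucleus, t2star)
    basis <- metabolite_basis(stats::setNames(list(m), m$name), protocol,
                              nucleus)
    A <- ideal_design(basis)
    if (fitter == "ideal") {
      s <- rowMeans(S)
      Mod(qr.solve(A, s))
    } else if (fitter == "ideal_modes") {
      K <- ncol(S)
      C <- max(K %/% 2 - 1, 0)
      psi <- phase_cycle_schedule(protocol)
      W <- exp(1i * outer(psi, -C:C)) / K
      Fm <- S %*% W
      TRs <- protocol$TR_ms / 1000
      df_j <- ppm_to_hz(nucleus, m$shift_ppm)
      p <- vapply(seq_len(2 * C + 1), function(ci) {
        Ac <- A * exp(1i * (ci - C - 1) * 2 * pi * df_j * TRs)
        Mod(qr.solve(Ac, Fm[, ci]))
      }, numeric(1))
      sqrt(sum(p^2))
    } else {
      psi <- phase_cycle_schedule(protocol)
      tn <- sample_times_ms(protocol)
      col <- as.vector(outer(seq_along(tn), seq_along(psi), function(n, k)
        bssfp_signal(m, steady_state_eval(protocol$flip_deg * pi / 180,
                                          psi[k], 0, tn[n]),
                     protocol$TR_ms, nucleus)))
      Mod(qr.solve(cbind(col), as.vector(S)))
    }
  }
  unname(one(metabolite) / one(water))
}

#' Convert fitted amplitudes to millimolar concentration maps
#'
#' `conc_j = |amp_j| / |amp_water| / calibration_j * water_ref_mM *
#' n_labels_water / n_labels_j`, with Glx additionally divided by
#' `(1 - glx_label_loss)`. Voxels whose water amplitude falls below
#' `water_floor` times the noise level are masked (`NA`), which prevents
#' the spurious overestimation where the water reference is unreliable.
#'
#' @param maps a `metabolite_maps` object (SNR units recommended).
#' @param water_map water reference amplitudes (same voxel ordering), e.g.
#'   the water column of the earliest-time-point fit.
#' @param cfg a [quant_config()].
#' @param protocol a [protocol_spec()].
#' @param metabolites named list of [metabolite_spec()]s matching the map
#'   columns; must contain `"water"`.
#' @param nucleus a [nucleus_field()].
#' @param noise_sd noise level of the water map (1 in SNR units).
#' @param water_floor mask threshold in noise SDs.
#' @param fitter,t2star calibration options, see [calibration_factor()].
#' @return matrix `[voxel, metabolite]` of concentrations in mM.
#' @export
quantify_maps <- function(maps, water_map, cfg, protocol, metabolites,
                          nucleus = nucleus_field(), noise_sd = 1,
                          water_floor = 3,
                          fitter = c("ideal", "ideal_modes", "linear"),
                          t2star = TRUE) {
  stopifnot(inherits(cfg, "quant_config"))
  fitter <- match.arg(fitter)
  iw <- match("water", names(metabolites))
  if (is.na(iw)) stop("metabolite table must contain 'water'")
  wamp <- Mod(as.vector(water_map))
  bad <- wamp < water_floor * noise_sd
  water <- metabolites[[iw]]
  M <- length(metabolites)
  conc <- matrix(NA_real_, nrow(maps$amplitudes), M,
                 dimnames = list(NULL, names(metabolites)))
  for (j in seq_len(M)) {
    m <- metabolites[[j]]
    cal <- calibration_factor(m, protocol, nucleus, water, fitter, t2star)
    v <- Mod(maps$amplitudes[, j]) / wamp / cal * cfg$water_ref_mM *
      water$n_labels / m$n_labels
    if (grepl("^glx", names(metabolites)[j], ignore.case = TRUE))
      v <- v / (1 - cfg$glx_label_loss)
    v[bad] <- NA_real_
    conc[, j] <- v
  }
  conc
}
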