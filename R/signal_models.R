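#' Evaluation point for the balanced SSFP steady state
#'
#' Collects the sequence and off-resonance parameters at which the bSSFP
#' steady state is evaluated: flip angle, RF phase increment per TR,
#' B0-related off-resonance and the time after excitation.
#'
#' @param alpha_rad flip angle, rad.
#' @param psi_rad RF phase increment per TR, rad (pi = standard alternation).
#' @param df0_Hz B0 off-resonance, Hz.
#' @param t_ms time after excitation, ms.
#' @return object of class `steady_state_eval`.
#' @export
steady_state_eval <- function(alpha_rad, psi_rad = pi, df0_Hz = 0, t_ms = 0) {
  stopifnot(alpha_rad >= 0, alpha_rad <= pi)
  structure(list(alpha_rad = alpha_rad, psi_rad = psi_rad,
                 df0_Hz = df0_Hz, t_ms = t_ms),
            class = "steady_state_eval")
}

check_relax <- function(metabolite) {
  if (metabolite$T1_ms <= 0 || metabolite$T2_ms <= 0)
    stop("non-positive relaxation times for '", metabolite$name, "'")
}

#' FISP (SSFP-FID) steady-state amplitude
#'
#' Analytical steady-state signal of a gradient-spoiled, non-RF-spoiled
#' sequence directly after excitation, as a fraction of M0. Equal to the
#' lowest configuration mode (complex mean over uniform intravoxel
#' dephasing) of the balanced steady state, which is how the expression is
#' validated against an isochromat simulation in the test suite.
#'
#' @param metabolite a [metabolite_spec()].
#' @param TR_ms repetition time, ms.
#' @param alpha_rad flip angle, rad.
#' @return real amplitude in `[0, 1]`.
#' @export
fisp_steady_state <- function(metabolite, TR_ms, alpha_rad) {
  check_relax(metabolite)
  stopifnot(TR_ms > 0, alpha_rad >= 0, alpha_rad <= pi)
  E1 <- exp(-TR_ms / metabolite$T1_ms)
  E2 <- exp(-TR_ms / metabolite$T2_ms)
  ca <- cos(alpha_rad)
  p <- 1 - E1 * ca - E2^2 * (E1 - ca)
  q <- E2 * (1 - E1) * (1 + ca)
  tan(alpha_rad / 2) * (1 - (E1 - ca) * (1 - E2^2) / sqrt(p^2 - q^2))
}

#' Balanced SSFP steady-state signal
#'
#' Complex transverse magnetization of one resonance under phase-cycled
#' bSSFP, including the T2 decay and phase evolution during the TR. With
#' `Phi = 2 pi (df_j + df0) TR` the per-TR phase and `theta = Phi - psi`,
#' the signal at time `t` after excitation is
#' \deqn{S(t) = \frac{(1-E_1)\sin\alpha\,(1 - E_2 e^{-i\theta})}
#'  {(1-E_1\cos\alpha)(1-E_2\cos\theta)-(E_1-\cos\alpha)(E_2-\cos\theta)E_2}
#'  \; e^{-t/T_2}\, e^{i (t/TR) \Phi}.}
#'
#' All of `psi_rad`, `df0_Hz` and `t_ms` may be vectors (recycled against
#' each other).
#'
#' @param metabolite a [metabolite_spec()].
#' @param eval a [steady_state_eval()].
#' @param TR_ms repetition time, ms.
#' @param nucleus a [nucleus_field()] used to convert the metabolite shift.
#' @return complex signal amplitude(s) as a fraction of M0.
#' @export
bssfp_signal <- function(metabolite, eval, TR_ms, nucleus = nucleus_field()) {
  check_relax(metabolite)
  stopifnot(TR_ms > 0)
  if (any(eval$t_ms < 0) || any(eval$t_ms > TR_ms))
    stop("t_ms must lie in [0, TR]")
  df_j <- ppm_to_hz(nucleus, metabolite$shift_ppm)
  E1 <- exp(-TR_ms / metabolite$T1_ms)
  E2 <- exp(-TR_ms / metabolite$T2_ms)
  sa <- sin(eval$alpha_rad); ca <- cos(eval$alpha_rad)
  Phi <- 2 * pi * (df_j + eval$df0_Hz) * TR_ms / 1000
  theta <- Phi - eval$psi_rad
  num <- (1 - E1) * sa * (1 - E2 * exp(-1i * theta))
  den <- (1 - E1 * ca) * (1 - E2 * cos(theta)) -
    (E1 - ca) * (E2 - cos(theta)) * E2
  num / den * exp(-eval$t_ms / metabolite$T2_ms) *
    exp(1i * (eval$t_ms / TR_ms) * Phi)
}

#' Simulated bSSFP frequency response
#'
#' Evaluates [bssfp_signal()] over grids of RF phase increment and B0
#' off-resonance at the protocol's sample times.
#'
#' @param metabolite a [metabolite_spec()].
#' @param protocol a [protocol_spec()].
#' @param psi_grid RF phase increments, rad.
#' @param df0_grid off-resonance values, Hz.
#' @param nucleus a [nucleus_field()].
#' @return complex array `[psi x df0 x t_n]`.
#' @export
frequency_response <- function(metabolite, protocol, psi_grid, df0_grid,
                               nucleus = nucleus_field()) {
  stopifnot(length(psi_grid) > 0, length(df0_grid) > 0)
  tn <- sample_times_ms(protocol)
  out <- array(0i, c(length(psi_grid), length(df0_grid), length(tn)))
  for (j in seq_along(df0_grid)) for (n in seq_along(tn)) {
    ev <- steady_state_eval(protocol$flip_deg * pi / 180, psi_grid,
                            df0_grid[j], tn[n])
    out[, j, n] <- bssfp_signal(metabolite, ev, protocol$TR_ms, nucleus)
  }
  out
}

#' Readout windows of a protocol
#'
#' Start/end times (ms after excitation) of the sampled windows: one
#' contiguous window for CSI (centered in TR for balanced sequences), one
#' window of width `TR * duty / n_echoes` around each echo center for
#' multi-echo trains.
#'
#' @param protocol a [protocol_spec()].
#' @return two-column matrix (start, end) in ms.
#' @export
readout_windows <- function(protocol) {
  if (protocol$encoding == "csi") {
    t0 <- if (protocol$sequence == "bssfp")
      (protocol$TR_ms - protocol$readout_ms) / 2 else 0
    cbind(t0, t0 + protocol$readout_ms)
  } else {
    w <- protocol$TR_ms * protocol$adc_duty / protocol$n_echoes
    te <- sample_times_ms(protocol)
    cbind(te - w / 2, te + w / 2)
  }
}

#' Matched-filter readout SNR factor
#'
#' Square root of the integrated squared signal decay over the sampled
#' readout windows, `sqrt(sum_w int exp(-2 t / tau) dt)` in sqrt(ms). The
#' decay constant is T2* for the FISP free-induction readout and T2 for
#' balanced sequences, whose gradient-recalled echoes refocus the
#' reversible dephasing so that the steady-state T2 term of the signal
#' model governs the decay across the readout.
#'
#' @param metabolite a [metabolite_spec()].
#' @param protocol a [protocol_spec()].
#' @return unitless-amplitude * sqrt(ms) matched-filter factor.
#' @export
readout_snr_factor <- function(metabolite, protocol) {
  check_relax(metabolite)
  win <- readout_windows(protocol)
  if (any(win[, 2] <= win[, 1])) stop("readout window of non-positive length")
  tau <- if (protocol$sequence == "bssfp") metabolite$T2_ms
         else metabolite$T2star_ms
  sqrt(sum(tau / 2 * (exp(-2 * win[, 1] / tau) - exp(-2 * win[, 2] / tau))))
}

rms_cycle_amplitude <- function(metabolite, protocol, nucleus,
                                df0 = c("average", "centered"),
                                n_df0 = 256) {
  df0 <- match.arg(df0)
  psi <- phase_cycle_schedule(protocol)
  a <- protocol$flip_deg * pi / 180
  if (df0 == "centered") {
    s <- bssfp_signal(metabolite, steady_state_eval(a, psi, 0, 0),
                      protocol$TR_ms, nucleus)
    return(sqrt(mean(Mod(s)^2)))
  }
  off <- (seq_len(n_df0) - 1) / n_df0 * 1000 / protocol$TR_ms
  s2 <- vapply(off, function(d) {
    s <- bssfp_signal(metabolite, steady_state_eval(a, psi, d, 0),
                      protocol$TR_ms, nucleus)
    mean(Mod(s)^2)
  }, numeric(1))
  sqrt(mean(s2))
}

#' Phase-cycled bSSFP signal efficiency
#'
#' Matched-filter combination of the K phase-cycled signals,
#' `sqrt(mean_k |S(psi_k)|^2)`, times the readout factor, per square root
#' of TR. By default the root-mean-square is additionally averaged over a
#' uniform off-resonance distribution spanning one banding period
#' (protocols are designed for whole-brain B0 spans of several periods);
#' `df0 = "centered"` evaluates at the metabolite's own resonance only.
#'
#' @param metabolite a [metabolite_spec()].
#' @param protocol a [protocol_spec()] with `sequence = "bssfp"`.
#' @param nucleus a [nucleus_field()].
#' @param df0 `"average"` (default) or `"centered"`.
#' @return efficiency in amplitude-equivalent per sqrt(ms).
#' @export
phase_cycled_efficiency <- function(metabolite, protocol,
                                    nucleus = nucleus_field(),
                                    df0 = c("average", "centered")) {
  if (protocol$K_phase_cycles < 1) stop("K_phase_cycles must be >= 1")
  rms_cycle_amplitude(metabolite, protocol, nucleus, df0) *
    readout_snr_factor(metabolite, protocol) / sqrt(protocol$TR_ms)
}

#' Signal efficiency of a protocol for one metabolite
#'
#' Steady-state amplitude times the matched-filter readout factor per
#' square root of TR; proportional to SNR per unit scan time. FISP
#' protocols use the analytical FISP amplitude, balanced protocols the
#' phase-cycled combination of [phase_cycled_efficiency()].
#'
#' @inheritParams phase_cycled_efficiency
#' @return efficiency in amplitude-equivalent per sqrt(ms).
#' @export
signal_efficiency <- function(metabolite, protocol,
                              nucleus = nucleus_field(),
                              df0 = c("average", "centered")) {
  if (protocol$sequence == "fisp") {
    fisp_steady_state(metabolite, protocol$TR_ms,
                      protocol$flip_deg * pi / 180) *
      readout_snr_factor(metabolite, protocol) / sqrt(protocol$TR_ms)
  } else if (protocol$sequence == "bssfp") {
    phase_cycled_efficiency(metabolite, protocol, nucleus, df0)
  } else stop("unknown sequence type '", protocol$sequence, "'")
}

#' Time-averaged RF power and SAR feasibility
#'
#' Rectangular-pulse scalar power model: the time-averaged power is
#' proportional to the squared pulse amplitude (flip / duration) times the
#' pulse duty cycle, `P = c * flip_deg^2 / (dur_ms * TR_ms)`. The shipped
#' calibration constant places the three protocol presets just inside the
#' 12 W limit of the head coil.
#'
#' @param protocol a [protocol_spec()].
#' @param scale_W calibration constant in W * ms^2 / deg^2.
#' @param limit_W allowed maximum time-averaged power, W.
#' @return list with `power_W` and logical `feasible`.
#' @export
sar_time_avg_power <- function(protocol, scale_W = 0.125, limit_W = 12) {
  P <- scale_W * protocol$flip_deg^2 / (protocol$rf_dur_ms * protocol$TR_ms)
  list(power_W = P, feasible = P <= limit_W)
}

#' Compare signal efficiencies across protocols
#'
#' @param protocols list of [protocol_spec()]s.
#' @param metabolites list of [metabolite_spec()]s.
#' @param reference name of the reference protocol (default: the first).
#' @param nucleus a [nucleus_field()].
#' @param df0 off-resonance handling, see [phase_cycled_efficiency()].
#' @return data.frame with one row per protocol x metabolite: efficiency
#'   and percent change versus the reference protocol.
#' @export
compare_protocols <- function(protocols, metabolites,
                              reference = NULL,
                              nucleus = nucleus_field(),
                              df0 = c("average", "centered")) {
  stopifnot(length(protocols) >= 2)
  pnames <- vapply(protocols, `[[`, "", "name")
  if (is.null(reference)) reference <- pnames[1]
  if (!reference %in% pnames)
    stop("reference protocol '", reference, "' not in the protocol list")
  eff <- sapply(protocols, function(p)
    vapply(metabolites, signal_efficiency, numeric(1), protocol = p,
           nucleus = nucleus, df0 = df0))
  eff <- matrix(eff, nrow = length(metabolites),
                dimnames = list(vapply(metabolites, `[[`, "", "name"), pnames))
  ref <- eff[, reference]
  out <- expand.grid(metabolite = rownames(eff), protocol = pnames,
                     stringsAsFactors = FALSE)
  out$efficiency <- as.vector(eff)
  out$pct_change <- 100 * (as.vector(eff) / rep(ref, length(pnames)) - 1)
  out
}
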