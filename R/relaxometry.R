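#' Non-localized spectroscopy series
#'
#' A stack of complex spectra acquired at increasing inversion or echo
#' times (or a single FID spectrum).
#'
#' @param spectra complex matrix `[frequency, time]`.
#' @param axis_Hz frequency axis (Hz, relative to the reference).
#' @param times_ms inversion/echo times; strictly increasing.
#' @param kind `"inversion_recovery"`, `"spin_echo"` or `"fid"`.
#' @return object of class `relax_series`.
#' @export
relax_series <- function(spectra, axis_Hz, times_ms,
                         kind = c("inversion_recovery", "spin_echo", "fid")) {
  kind <- match.arg(kind)
  spectra <- as.matrix(spectra)
  stopifnot(nrow(spectra) == length(axis_Hz),
            ncol(spectra) == length(times_ms))
  if (kind != "fid" && length(times_ms) < 6)
    stop("need at least 6 time points for a stable fit")
  if (any(diff(times_ms) <= 0)) stop("times must be strictly increasing")
  structure(list(spectra = spectra, axis_Hz = axis_Hz,
                 times_ms = times_ms, kind = kind),
            class = "relax_series")
}

lorentz_line <- function(f, f0, gamma) 1 / (1 + ((f - f0) / gamma)^2)

# Variable-projection engine for the combined spectral-temporal models:
# S(f, t) = sum_j a_j * L(f; f0_j, gamma_j) * g_j(t; theta_j), with complex
# amplitudes a_j solved linearly and the nonlinear parameters refined by
# Levenberg-Marquardt on the stacked real/imaginary residuals.
varpro_fit <- function(series, n_lines, g_fun, th0, lower, upper,
                       f0_init, gamma_init, n_temporal,
                       f0_starts = c(0), max_iter = 200) {
  f <- series$axis_Hz
  tt <- series$times_ms
  Y <- as.vector(series$spectra)
  build <- function(par) {
    B <- matrix(0, length(f) * length(tt), 0)
    for (j in seq_len(n_lines)) {
      p <- par[((j - 1) * (2 + n_temporal) + 1):(j * (2 + n_temporal))]
      L <- lorentz_line(f, p[1], p[2])
      g <- g_fun(tt, p[-(1:2)])
      B <- cbind(B, as.vector(outer(L, g)))
    }
    B
  }
  solve_amp <- function(B) {
    qrB <- qr(B)
    co <- qr.coef(qrB, cbind(Re(Y), Im(Y)))
    co[is.na(co)] <- 0
    complex(real = co[, 1], imaginary = co[, 2])
  }
  resid_fun <- function(par) {
    B <- build(par)
    a <- tryCatch(solve_amp(B), error = function(e) rep(0i, ncol(B)))
    r <- Y - B %*% a
    c(Re(r), Im(r))
  }
  best <- NULL
  for (off in f0_starts) {
    par0 <- numeric(0)
    for (j in seq_len(n_lines))
      par0 <- c(par0, f0_init[j] + off, gamma_init[j], th0[[j]])
    lw <- numeric(0); up <- numeric(0)
    for (j in seq_len(n_lines)) {
      lw <- c(lw, f0_init[j] - 30, 1e-2, lower[[j]])
      up <- c(up, f0_init[j] + 30, 1e3, upper[[j]])
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fun, lower = lw, upper = up,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stop("relaxometry fit did not converge from any start")
  par <- best$fit$par
  B <- build(par)
  a <- solve_amp(B)
  list(par = par, amps = a, rss = best$rss,
       converged = best$fit$info %in% 1:4,
       n_temporal = n_temporal)
}

#' Fit T1 from an inversion-recovery spectral series
#'
#' Simultaneous nonlinear least squares of one three-parameter Lorentzian
#' line per metabolite times the inversion-recovery amplitude model
#' `S(TI) = a (1 - b exp(-TI / T1))` over the 2-D (frequency x TI)
#' surface. The inversion efficiency `b` is bounded to `[0, 2.2]` to
#' absorb imperfect adiabatic inversion.
#'
#' @param series a [relax_series()] of kind `"inversion_recovery"`.
#' @param metabolites named list of [metabolite_spec()]s giving the
#'   starting shifts and relaxation guesses.
#' @param nucleus a [nucleus_field()].
#' @return data.frame per metabolite: complex amplitude, `shift_ppm`,
#'   linewidth `gamma_Hz`, `T1_ms`, `b`, plus fit diagnostics.
#' @export
fit_inversion_recovery <- function(series, metabolites,
                                   nucleus = nucleus_field()) {
  stopifnot(series$kind == "inversion_recovery")
  M <- length(metabolites)
  f0 <- vapply(metabolites, function(m) ppm_to_hz(nucleus, m$shift_ppm),
               numeric(1))
  g_ir <- function(t, th) 1 - th[2] * exp(-t / th[1])
  res <- varpro_fit(series, M, g_ir,
                    th0 = lapply(metabolites, function(m) c(m$T1_ms, 1.9)),
                    lower = rep(list(c(1, 0)), M),
                    upper = rep(list(c(5000, 2.2)), M),
                    f0_init = f0,
                    gamma_init = vapply(metabolites, function(m)
                      1 / (pi * m$T2star_ms) * 1000 / 2, numeric(1)),
                    n_temporal = 2,
                    f0_starts = c(0, -12, 12))
  p <- matrix(res$par, ncol = M)
  out <- data.frame(
    metabolite = names(metabolites),
    shift_ppm = p[1, ] / nucleus$f_larmor_MHz + nucleus$ref_ppm,
    gamma_Hz = p[2, ], T1_ms = p[3, ], b = p[4, ])
  out$amplitude <- res$amps
  if (any(out$b > 2.2 - 1e-6))
    warning("inversion efficiency b at its bound (imperfect inversion)")
  attr(out, "rss") <- res$rss
  attr(out, "converged") <- res$converged
  out
}

#' Fit T2 from a spin-echo spectral series
#'
#' As [fit_inversion_recovery()] with the mono-exponential decay
#' `S(TE) = a exp(-TE / T2)`. With `biexp_water = TRUE` the water
#' resonance receives two shared-lineshape components with separate T2
#' values and linear amplitudes; the reported `long_fraction` is the
#' amplitude fraction of the slower component.
#'
#' @param series a [relax_series()] of kind `"spin_echo"`.
#' @param metabolites named list of [metabolite_spec()]s; the water entry
#'   must be named `"water"` when `biexp_water` is set.
#' @param biexp_water model ventricular water with a second T2 component.
#' @param nucleus a [nucleus_field()].
#' @return data.frame per component with `T2_ms`, amplitudes and, for
#'   bi-exponential water, `long_fraction` as an attribute.
#' @export
fit_spin_echo <- function(series, metabolites, biexp_water = FALSE,
                          nucleus = nucleus_field()) {
  stopifnot(series$kind == "spin_echo")
  mets <- metabolites
  comp_names <- names(mets)
  T2_0 <- vapply(mets, `[[`, numeric(1), "T2_ms")
  if (biexp_water) {
    iw <- match("water", names(mets))
    if (is.na(iw)) stop("biexp_water requires a metabolite named 'water'")
    mets <- c(mets, list(water_long = mets[[iw]]))
    comp_names <- c(comp_names, "water_long")
    lt <- attr(metabolites[[iw]], "long_T2_ms") %||% (6 * T2_0[iw])
    T2_0 <- c(T2_0, lt)
  }
  M <- length(mets)
  f0 <- vapply(mets, function(m) ppm_to_hz(nucleus, m$shift_ppm),
               numeric(1))
  g_se <- function(t, th) exp(-t / th[1])
  res <- varpro_fit(series, M, g_se,
                    th0 = as.list(T2_0),
                    lower = rep(list(1), M),
                    upper = rep(list(5000), M),
                    f0_init = f0,
                    gamma_init = vapply(mets, function(m)
                      1 / (pi * m$T2star_ms) * 1000 / 2, numeric(1)),
                    n_temporal = 1,
                    f0_starts = c(0, -12, 12))
  p <- matrix(res$par, ncol = M)
  out <- data.frame(
    metabolite = comp_names,
    shift_ppm = p[1, ] / nucleus$f_larmor_MHz + nucleus$ref_ppm,
    gamma_Hz = p[2, ], T2_ms = p[3, ])
  out$amplitude <- res$amps
  if (biexp_water) {
    iw <- match("water", comp_names)
    il <- match("water_long", comp_names)
    tot <- Mod(res$amps[iw]) + Mod(res$amps[il])
    frac <- if (tot > 0) Mod(res$amps[il]) / tot else NA_real_
    if (!is.na(frac) && (frac < 1e-3 || frac > 1 - 1e-3))
      attr(out, "degenerate") <- TRUE
    attr(out, "long_fraction") <- frac
  }
  attr(out, "rss") <- res$rss
  attr(out, "converged") <- res$converged
  out
}

#' Fit Lorentzian peaks of a single spectrum (T2* and shifts)
#'
#' Fits one complex-amplitude Lorentzian per metabolite to a single
#' spectrum; T2* follows from the linewidth as `1 / (pi * FWHM)` and the
#' chemical shift is reported on the ppm axis. Peaks whose fitted
#' amplitude falls below `noise_floor` are dropped.
#'
#' @param series a [relax_series()] of kind `"fid"` (single time column).
#' @param metabolites named list of starting [metabolite_spec()]s.
#' @param noise_floor amplitude threshold for reporting a peak.
#' @param nucleus a [nucleus_field()].
#' @return data.frame per detected peak: amplitude, `shift_ppm`,
#'   `T2star_ms`.
#' @export
fit_fid_peaks <- function(series, metabolites, noise_floor = 0,
                          nucleus = nucleus_field()) {
  stopifnot(series$kind == "fid")
  if (all(Mod(series$spectra) < .Machine$double.eps))
    return(data.frame(metabolite = character(), amplitude = complex(),
                      shift_ppm = numeric(), T2star_ms = numeric()))
  M <- length(metabolites)
  f0 <- vapply(metabolites, function(m) ppm_to_hz(nucleus, m$shift_ppm),
               numeric(1))
  g_one <- function(t, th) rep(1, length(t))
  res <- varpro_fit(series, M, function(t, th) rep(1, length(t)),
                    th0 = rep(list(numeric(0)), M),
                    lower = rep(list(numeric(0)), M),
                    upper = rep(list(numeric(0)), M),
                    f0_init = f0,
                    gamma_init = vapply(metabolites, function(m)
                      1 / (pi * m$T2star_ms) * 1000 / 2, numeric(1)),
                    n_temporal = 0,
                    f0_starts = c(0, -12, 12))
  p <- matrix(res$par, ncol = M)
  out <- data.frame(
    metabolite = names(metabolites),
    shift_ppm = p[1, ] / nucleus$f_larmor_MHz + nucleus$ref_ppm,
    T2star_ms = 1000 / (pi * 2 * p[2, ]))
  out$amplitude <- res$amps
  out[Mod(out$amplitude) >= noise_floor, ]
}
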