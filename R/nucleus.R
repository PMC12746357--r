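#' Deuterium nucleus / field description
#'
#' Bundles the static field strength with the gyromagnetic ratio of
#' deuterium and the ppm reference so that chemical shifts on the ppm axis
#' can be converted to Hz. The ppm reference maps to 0 Hz; by convention the
#' scanner frequency is set on the water resonance at 4.70 ppm.
#'
#' @param B0_T static field in tesla.
#' @param gamma_MHz_per_T gyromagnetic ratio in MHz/T (6.536 for 2H).
#' @param ref_ppm ppm value mapped to 0 Hz (water, 4.70).
#' @return object of class `nucleus_field` with the Larmor frequency in MHz.
#' @export
nucleus_field <- function(B0_T = 9.4, gamma_MHz_per_T = 6.536, ref_ppm = 4.70) {
  stopifnot(B0_T > 0, gamma_MHz_per_T > 0)
  structure(
    list(B0_T = B0_T,
         gamma_MHz_per_T = gamma_MHz_per_T,
         f_larmor_MHz = B0_T * gamma_MHz_per_T,
         ref_ppm = ref_ppm),
    class = "nucleus_field")
}

#' Convert a chemical shift in ppm to an off-resonance frequency in Hz
#'
#' The Larmor frequency in MHz equals the Hz-per-ppm scale, so the
#' conversion is `(ppm - ref_ppm) * f_larmor_MHz`. Resonances upfield of the
#' reference (lower ppm) come out negative.
#'
#' @param nucleus a [nucleus_field()].
#' @param ppm chemical shift(s) on the ppm axis.
#' @return off-resonance in Hz relative to the reference.
#' @export
ppm_to_hz <- function(nucleus, ppm) {
  (ppm - nucleus$ref_ppm) * nucleus$f_larmor_MHz
}

#' One deuterated resonance with its relaxation times
#'
#' @param name label, e.g. `"glucose"`.
#' @param shift_ppm chemical shift on the ppm axis (water = 4.70).
#' @param T1_ms,T2_ms,T2star_ms relaxation times in ms; must satisfy
#'   `0 < T2* <= T2 <= T1`.
#' @param n_labels deuterons per molecule contributing to the resonance
#'   (water 1, glucose 2, Glx 1 effective site, lactate 3).
#' @return object of class `metabolite_spec`.
#' @export
metabolite_spec <- function(name, shift_ppm, T1_ms, T2_ms, T2star_ms,
                            n_labels = 1L) {
  if (!(T2star_ms > 0 && T2star_ms <= T2_ms && T2_ms <= T1_ms))
    stop("relaxation times must satisfy 0 < T2* <= T2 <= T1 (got ",
         T2star_ms, ", ", T2_ms, ", ", T1_ms, " ms for '", name, "')")
  if (n_labels < 1) stop("n_labels must be >= 1")
  structure(
    list(name = name, shift_ppm = shift_ppm, T1_ms = T1_ms, T2_ms = T2_ms,
         T2star_ms = T2star_ms, n_labels = as.integer(n_labels)),
    class = "metabolite_spec")
}

#' @export
print.metabolite_spec <- function(x, ...) {
  cat(sprintf("<metabolite %s: %.2f ppm, T1 %g / T2 %g / T2* %g ms, %d label(s)>\n",
              x$name, x$shift_ppm, x$T1_ms, x$T2_ms, x$T2star_ms, x$n_labels))
  invisible(x)
}

#' Load a shipped metabolite table
#'
#' The package ships the measured relaxation times and chemical shifts of
#' the four deuterium resonances at 9.4 T, one block for the in vivo brain
#' values and one for the multi-compound phantom. The in vivo water entry
#' additionally carries the ventricular long-T2 compartment (T2 = 293 ms,
#' fraction 0.18) as attributes `long_T2_ms` / `long_fraction`.
#'
#' @param set `"in_vivo"` or `"phantom"`.
#' @return named list of [metabolite_spec()] objects.
#' @export
dmi_metabolites <- function(set = c("in_vivo", "phantom")) {
  set <- match.arg(set)
  path <- system.file("extdata", "metabolites.yaml", package = "pcdmi",
                      mustWork = TRUE)
  tab <- yaml::read_yaml(path)[[set]]
  out <- lapply(names(tab), function(nm) {
    m <- tab[[nm]]
    sp <- metabolite_spec(nm, m$shift_ppm, m$T1_ms, m$T2_ms, m$T2star_ms,
                          m$n_labels)
    if (!is.null(m$long_T2_ms)) {
      attr(sp, "long_T2_ms") <- m$long_T2_ms
      attr(sp, "long_fraction") <- m$long_fraction
    }
    sp
  })
  names(out) <- names(tab)
  out
}
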