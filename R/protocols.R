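#' Acquisition protocol description
#'
#' Describes one spectral-spatial 2H acquisition: encoding scheme, steady
#' state sequence, timing, phase cycling, k-space weighting and geometry.
#' Use [dmi_protocol()] to load the shipped presets.
#'
#' @param name protocol label.
#' @param encoding `"csi"` (phase encoding in all three dimensions with a
#'   spectral readout per excitation) or `"multi_echo"` (frequency-encoded
#'   echo train; spectral separation from inter-echo phase evolution).
#' @param sequence `"fisp"` (gradient-spoiled, non-RF-spoiled steady state)
#'   or `"bssfp"` (fully balanced).
#' @param TR_ms repetition time, ms.
#' @param flip_deg nominal flip angle, degrees.
#' @param rf_dur_ms rectangular RF pulse duration, ms.
#' @param adc_duty fraction of TR spent sampling.
#' @param K_phase_cycles number of RF phase-increment cycles (1 = single
#'   180 degree increment).
#' @param n_averages maximum number of acquisitions per k-space point.
#' @param weighting `"hamming"` acquisition weighting or `"uniform"`.
#' @param mask `"full"` or `"elliptical"` k-space coverage.
#' @param fov_mm,matrix 3-vectors of field of view (mm) and encoding matrix.
#' @param readout_ms CSI spectral readout duration (ms).
#' @param n_samples number of simulated spectral samples over the CSI readout.
#' @param echo_spacing_ms,n_echoes multi-echo train definition.
#' @param read_axis index (1..3) of the frequency-encode axis (multi-echo).
#' @return object of class `protocol_spec`.
#' @export
protocol_spec <- function(name, encoding = c("csi", "multi_echo"),
                          sequence = c("fisp", "bssfp"),
                          TR_ms, flip_deg, rf_dur_ms, adc_duty,
                          K_phase_cycles = 1L, n_averages = 1L,
                          weighting = c("hamming", "uniform"),
                          mask = c("full", "elliptical"),
                          fov_mm, matrix,
                          readout_ms = NULL, n_samples = NULL,
                          echo_spacing_ms = NULL, n_echoes = NULL,
                          read_axis = NULL) {
  encoding <- match.arg(encoding)
  sequence <- match.arg(sequence)
  weighting <- match.arg(weighting)
  mask <- match.arg(mask)
  stopifnot(TR_ms > 0, rf_dur_ms > 0, adc_duty > 0, adc_duty <= 1,
            flip_deg >= 0, K_phase_cycles >= 1, n_averages >= 1,
            length(fov_mm) == 3, length(matrix) == 3, all(fov_mm > 0),
            all(matrix >= 1))
  if (encoding == "csi") {
    if (is.null(readout_ms) || readout_ms <= 0)
      stop("csi protocols need a positive readout_ms")
    if (is.null(n_samples)) n_samples <- 32L
  } else {
    if (is.null(n_echoes) || n_echoes < 1)
      stop("multi_echo protocols need n_echoes >= 1")
    if (is.null(echo_spacing_ms) || echo_spacing_ms <= 0)
      stop("multi_echo protocols need a positive echo_spacing_ms")
    if (echo_spacing_ms * n_echoes > TR_ms)
      stop("echo train (", echo_spacing_ms * n_echoes,
           " ms) does not fit into TR (", TR_ms, " ms)")
    if (is.null(read_axis)) read_axis <- 1L
  }
  structure(
    list(name = name, encoding = encoding, sequence = sequence,
         TR_ms = TR_ms, flip_deg = flip_deg, rf_dur_ms = rf_dur_ms,
         adc_duty = adc_duty, K_phase_cycles = as.integer(K_phase_cycles),
         n_averages = as.integer(n_averages), weighting = weighting,
         mask = mask, fov_mm = as.numeric(fov_mm),
         matrix = as.integer(matrix), readout_ms = readout_ms,
         n_samples = if (!is.null(n_samples)) as.integer(n_samples),
         echo_spacing_ms = echo_spacing_ms,
         n_echoes = if (!is.null(n_echoes)) as.integer(n_echoes),
         read_axis = if (!is.null(read_axis)) as.integer(read_axis)),
    class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf(paste0("<protocol %s: %s/%s, TR %g ms, FA %g deg, duty %g, ",
                     "K = %d, %d avg, %s/%s, %dx%dx%d over %gx%gx%g mm>\n"),
              x$name, x$encoding, x$sequence, x$TR_ms, x$flip_deg,
              x$adc_duty, x$K_phase_cycles, x$n_averages, x$weighting,
              x$mask, x$matrix[1], x$matrix[2], x$matrix[3],
              x$fov_mm[1], x$fov_mm[2], x$fov_mm[3]))
  invisible(x)
}

#' Load a shipped protocol preset
#'
#' @param name one of `"csi"`, `"csi_pc_bssfp"`, `"me_pc_bssfp"`.
#' @return a [protocol_spec()].
#' @export
dmi_protocol <- function(name = c("csi", "csi_pc_bssfp", "me_pc_bssfp")) {
  path <- system.file("extdata", "protocols.yaml", package = "pcdmi",
                      mustWork = TRUE)
  tab <- yaml::read_yaml(path)
  if (!name[1] %in% names(tab))
    stop("unknown protocol preset '", name[1], "'; available: ",
         paste(names(tab), collapse = ", "))
  p <- tab[[name[1]]]
  do.call(protocol_spec, c(list(name = name[1]), p))
}

#' RF phase-increment schedule of a phase-cycled protocol
#'
#' The K phase cycles use per-TR RF phase increments
#' `psi_k = 180 + k * 360 / K` degrees, k = 0..K-1, so a single cycle is the
#' usual 180 degree alternation.
#'
#' @param protocol a [protocol_spec()] (or an integer K).
#' @return increments in radians.
#' @export
phase_cycle_schedule <- function(protocol) {
  K <- if (inherits(protocol, "protocol_spec")) protocol$K_phase_cycles
       else as.integer(protocol)
  stopifnot(K >= 1)
  pi + 2 * pi * (seq_len(K) - 1) / K
}

#' Echo / sample time grid of a protocol
#'
#' CSI: `n_samples` uniform samples over the readout window. Multi-echo:
#' the echo centers, with the echo train centered inside TR. Times are ms
#' after the RF pulse.
#'
#' @param protocol a [protocol_spec()].
#' @return numeric vector of sample times, ms.
#' @export
sample_times_ms <- function(protocol) {
  if (protocol$encoding == "csi") {
    t0 <- if (protocol$sequence == "bssfp")
      (protocol$TR_ms - protocol$readout_ms) / 2 else 0
    t0 + protocol$readout_ms * (seq_len(protocol$n_samples) - 0.5) /
      protocol$n_samples
  } else {
    sp <- protocol$echo_spacing_ms
    (protocol$TR_ms - (protocol$n_echoes - 1) * sp) / 2 +
      (seq_len(protocol$n_echoes) - 1) * sp
  }
}

#' Total scan time implied by a protocol's weighting scheme
#'
#' Sums the acquisition-weight grid over phase-encode space times phase
#' cycles times TR. For multi-echo protocols a whole read line is acquired
#' per TR, so the read axis does not multiply the count.
#'
#' @param protocol a [protocol_spec()].
#' @return scan time in seconds, with attribute `n_acquisitions`.
#' @export
scan_time_s <- function(protocol) {
  w <- acquisition_weights(protocol)
  n <- sum(w$weights)
  if (protocol$encoding == "multi_echo")
    n <- n / protocol$matrix[protocol$read_axis]
  n <- n * protocol$K_phase_cycles
  structure(n * protocol$TR_ms / 1000, n_acquisitions = n)
}
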