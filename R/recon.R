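#' Multi-channel raw acquisition container
#'
#' Complex k-space data over `[channel, kx, ky, kz, sample, phase_cycle]`
#' together with pure-noise samples for prewhitening, the
#' acquisition-weight grid (averages are stored already combined, with
#' per-point noise variance `1 / w`), and acquisition metadata.
#'
#' @param data complex 6-D array `[ch, kx, ky, kz, sample, cycle]`.
#' @param noise complex matrix `[ch, n]` of noise-only samples
#'   (`n >= 10 * channels`).
#' @param weights acquisition-weight grid on the k-space matrix.
#' @param protocol a [protocol_spec()].
#' @param nucleus a [nucleus_field()].
#' @param seed RNG seed recorded for provenance, or `NULL`.
#' @param prewhitened logical flag.
#' @return object of class `dmi_raw`.
#' @export
dmi_raw <- function(data, noise, weights, protocol, nucleus,
                    seed = NULL, prewhitened = FALSE) {
  stopifnot(length(dim(data)) == 6L, is.matrix(noise))
  if (ncol(noise) < 10 * nrow(noise))
    stop("need at least 10 noise samples per channel")
  if (!all(dim(data)[2:4] == protocol$matrix))
    stop("k-space dimensions do not match the protocol matrix")
  if (dim(data)[6] != protocol$K_phase_cycles)
    stop("phase-cycle axis does not match the protocol")
  structure(list(data = data, noise = noise, weights = weights,
                 protocol = protocol, nucleus = nucleus, seed = seed,
                 prewhitened = prewhitened),
            class = "dmi_raw")
}

#' Noise-prewhiten a raw acquisition
#'
#' Estimates the channel noise covariance from the noise-only samples and
#' applies the inverse Cholesky factor to data and noise so that the
#' transformed channel noise has identity covariance. Deterministic given
#' the stored noise samples.
#'
#' @param raw a [dmi_raw()].
#' @param ridge relative ridge added to the covariance if it is not
#'   positive definite (with a warning).
#' @return a prewhitened [dmi_raw()].
#' @export
prewhiten <- function(raw, ridge = 1e-8) {
  if (isTRUE(raw$prewhitened)) return(raw)
  nc <- nrow(raw$noise)
  n <- ncol(raw$noise)
  cov <- raw$noise %*% Conj(t(raw$noise)) / (n - 1)
  L <- tryCatch(chol_complex(cov), error = function(e) {
    warning("noise covariance not positive definite; ridge-regularizing")
    chol_complex(cov + diag(ridge * max(Re(diag(cov))), nc))
  })
  d <- dim(raw$data)
  flat <- matrix(raw$data, nrow = nc)
  white <- forwardsolve_complex(L, flat)
  dim(white) <- d
  raw$data <- white
  raw$noise <- forwardsolve_complex(L, raw$noise)
  raw$prewhitened <- TRUE
  raw$whitener <- L
  raw
}

#' Reconstruct per-channel image series in SNR units
#'
#' Zero-pads the (prewhitened, average-combined) k-space to twice the
#' encoding matrix, applies a unitary 3-D FFT per channel, sample and phase
#' cycle, and scales the result so that unit-variance per-acquisition
#' k-space noise maps to unit-variance image noise. With acquisition
#' weights `w`, the averaged k-space point carries noise variance `1 / w`
#' and the uniform image noise variance after a unitary FFT over `P` padded
#' points is `sum(1 / w) / P`; dividing by its square root yields SNR
#' units.
#'
#' @param raw a prewhitened [dmi_raw()].
#' @return object of class `image_series`: complex
#'   `img[x, y, z, sample, cycle, channel]` on the doubled grid,
#'   `is_snr_units` flag and voxel size.
#' @export
reconstruct <- function(raw) {
  if (!isTRUE(raw$prewhitened))
    stop("reconstruct() expects prewhitened data; call prewhiten() first")
  d <- dim(raw$data)
  nc <- d[1]; mat <- d[2:4]; ns <- d[5]; K <- d[6]
  pad <- 2L * mat
  P <- prod(pad)
  w <- raw$weights
  noise_var <- sum(1 / w[w > 0]) / P
  scl <- 1 / sqrt(noise_var)
  ctr_src <- mat %/% 2 + 1
  ctr_dst <- pad %/% 2 + 1
  ix <- lapply(1:3, function(a)
    ctr_dst[a] - ctr_src[a] + seq_len(mat[a]))
  img <- array(0i, c(pad, ns, K, nc))
  for (ch in seq_len(nc)) for (s in seq_len(ns)) for (k in seq_len(K)) {
    ksp <- array(0i, pad)
    ksp[ix[[1]], ix[[2]], ix[[3]]] <- raw$data[ch, , , , s, k]
    img[, , , s, k, ch] <- kspace_to_img(ksp) * scl
  }
  structure(list(img = img, is_snr_units = TRUE,
                 voxel_mm = raw$protocol$fov_mm / pad,
                 protocol = raw$protocol, nucleus = raw$nucleus,
                 combine_weights = NULL),
            class = "image_series")
}

#' Adaptive coil combination
#'
#' Combines channels with per-voxel unit-norm matched-filter weights
#' computed from the image volume averaged across the sample and
#' phase-cycle dimensions (the rank-one principal component of the
#' averaged per-voxel channel covariance). The same weights are applied to
#' every sample and phase cycle, and unit-norm weights preserve the SNR
#' units of the input.
#'
#' @param series per-channel `image_series` from [reconstruct()].
#' @return combined `image_series` with `img[x, y, z, sample, cycle]` and
#'   the applied `combine_weights[x, y, z, channel]`.
#' @export
adaptive_combine <- function(series) {
  d <- dim(series$img)
  nc <- d[6]
  avg <- apply(series$img, c(1, 2, 3, 6), mean)
  nrmsq <- apply(avg, c(1, 2, 3), function(v) sum(Mod(v)^2))
  nrm <- sqrt(nrmsq)
  nrm[nrm == 0] <- 1
  wts <- sweep(avg, c(1, 2, 3), nrm, "/")
  out <- array(0i, d[1:5])
  for (s in seq_len(d[4])) for (k in seq_len(d[5])) {
    acc <- array(0i, d[1:3])
    for (ch in seq_len(nc))
      acc <- acc + Conj(wts[, , , ch]) * series$img[, , , s, k, ch]
    out[, , , s, k] <- acc
  }
  series$img <- out
  series$combine_weights <- wts
  series
}
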