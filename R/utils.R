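# Small array / FFT helpers shared across the reconstruction and
# simulation code. Convention: image and k-space arrays are (x, y, z) with
# the DC component at index N %/% 2 + 1 after fftshift.

fftshift_idx <- function(N) c((N %/% 2 + 1):N, 1:(N %/% 2))
ifftshift_idx <- function(N) {
  h <- (N + 1) %/% 2
  c((h + 1):N, 1:h)
}

fftshift3 <- function(x) x[fftshift_idx(dim(x)[1]), fftshift_idx(dim(x)[2]),
                           fftshift_idx(dim(x)[3]), drop = FALSE]
ifftshift3 <- function(x) x[ifftshift_idx(dim(x)[1]), ifftshift_idx(dim(x)[2]),
                            ifftshift_idx(dim(x)[3]), drop = FALSE]

# unitary 3-D FFTs between centered image space and centered k-space
img_to_kspace <- function(img) {
  fftshift3(stats::fft(ifftshift3(img))) / sqrt(length(img))
}
kspace_to_img <- function(ksp) {
  fftshift3(stats::fft(ifftshift3(ksp), inverse = TRUE)) / sqrt(length(ksp))
}

# complex standard normal with unit variance (0.5 per quadrature)
rcnorm <- function(n) complex(real = stats::rnorm(n, sd = sqrt(0.5)),
                              imaginary = stats::rnorm(n, sd = sqrt(0.5)))

# Cholesky factor (lower triangular L with A = L %*% Conj(t(L))) of a
# Hermitian positive-definite matrix; base chol() is real-only.
chol_complex <- function(A) {
  n <- nrow(A)
  L <- matrix(0i, n, n)
  for (j in seq_len(n)) {
    s <- Re(A[j, j]) - sum(Mod(L[j, seq_len(j - 1)])^2)
    if (s <= 0) stop("matrix not positive definite")
    L[j, j] <- sqrt(s)
    if (j < n) for (i in (j + 1):n) {
      L[i, j] <- (A[i, j] - sum(L[i, seq_len(j - 1)] *
                                  Conj(L[j, seq_len(j - 1)]))) / L[j, j]
    }
  }
  L
}

# forward substitution solve L x = b for lower-triangular complex L
forwardsolve_complex <- function(L, B) {
  n <- nrow(L)
  B <- as.matrix(B)
  X <- matrix(0i, n, ncol(B))
  for (i in seq_len(n)) {
    acc <- if (i > 1) L[i, 1:(i - 1), drop = FALSE] %*% X[1:(i - 1), ,
                                                          drop = FALSE]
           else 0i
    X[i, ] <- (B[i, ] - acc) / L[i, i]
  }
  X
}
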