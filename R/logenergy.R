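# Wavelet log-energy features: successive differences of mean log-magnitude
# Fourier spectra of the DWT subbands across decomposition levels.

#' Specification of the log-energy feature
#'
#' @param level wavelet decomposition depth (>= 1).
#' @param wavelet wavelet basis; only `"haar"` is implemented.
#' @param epsilon positive stabiliser added inside the logarithm (the Haar
#'   detail subbands of flat regions are exactly zero, where `log(abs(.))`
#'   would be `-Inf`).
#' @return a `log_energy_spec` list.
#' @export
log_energy_spec <- function(level = 2L, wavelet = "haar", epsilon = 1e-12) {
  level <- as.integer(level)
  if (is.na(level) || level < 1L) abort_validation("wavelet level must be >= 1")
  if (!identical(wavelet, "haar")) abort_validation("only the haar wavelet is supported")
  if (epsilon <= 0) abort_validation("epsilon must be positive")
  structure(list(level = level, wavelet = wavelet, epsilon = epsilon),
            class = "log_energy_spec")
}

# Single-level orthonormal 2-D Haar transform. Odd trailing rows/cols are
# dropped. Returns approximation (a), horizontal (h), vertical (v) and
# diagonal (d) subbands at half resolution.
haar_dwt2 <- function(x) {
  h <- nrow(x) - nrow(x) %% 2L
  w <- ncol(x) - ncol(x) %% 2L
  x <- x[seq_len(h), seq_len(w), drop = FALSE]
  r1 <- x[seq(1L, h, 2L), , drop = FALSE]
  r2 <- x[seq(2L, h, 2L), , drop = FALSE]
  lo_r <- (r1 + r2) / sqrt(2)   # filter along rows (vertical direction)
  hi_r <- (r1 - r2) / sqrt(2)
  cA <- (lo_r[, seq(1L, w, 2L), drop = FALSE] + lo_r[, seq(2L, w, 2L), drop = FALSE]) / sqrt(2)
  cH <- (hi_r[, seq(1L, w, 2L), drop = FALSE] + hi_r[, seq(2L, w, 2L), drop = FALSE]) / sqrt(2)
  cV <- (lo_r[, seq(1L, w, 2L), drop = FALSE] - lo_r[, seq(2L, w, 2L), drop = FALSE]) / sqrt(2)
  cD <- (hi_r[, seq(1L, w, 2L), drop = FALSE] - hi_r[, seq(2L, w, 2L), drop = FALSE]) / sqrt(2)
  list(a = cA, h = cH, v = cV, d = cD)
}

# shift the zero-frequency component of a 2-D spectrum to the centre
fftshift2 <- function(x) {
  h <- nrow(x); w <- ncol(x)
  sr <- c(seq.int(floor(h / 2) + 1L, h), seq_len(floor(h / 2)))
  sc <- c(seq.int(floor(w / 2) + 1L, w), seq_len(floor(w / 2)))
  x[sr, sc, drop = FALSE]
}

mean_log_spectrum <- function(band, epsilon) {
  mean(log(abs(fftshift2(stats::fft(band))) + epsilon))
}

#' Log-energy wavelet features
#'
#' At each level `i = 1..level` the image (cascading the approximation
#' subband) is decomposed into approximation/horizontal/vertical/diagonal
#' Haar subbands; `A(i)..D(i)` are the means of the log-magnitude centred
#' Fourier spectra of the four subbands. The features are the summed
#' successive differences `RA = sum(diff(A))` and likewise `RH`, `RV`, `RD`.
#' With `level = 1` all four features are exactly 0 (an empty difference).
#'
#' @param img grayscale image matrix with both sides at least `2^level`.
#' @param spec a [log_energy_spec()].
#' @return named numeric vector `c(RA, RH, RV, RD)`.
#' @export
log_energy <- function(img, spec = log_energy_spec()) {
  assert_gray_image(img)
  if (min(dim(img)) < 2^spec$level) {
    abort_validation("image too small for the requested wavelet level")
  }
  A <- H <- V <- D <- numeric(spec$level)
  cur <- img
  for (i in seq_len(spec$level)) {
    sb <- haar_dwt2(cur)
    A[i] <- mean_log_spectrum(sb$a, spec$epsilon)
    H[i] <- mean_log_spectrum(sb$h, spec$epsilon)
    V[i] <- mean_log_spectrum(sb$v, spec$epsilon)
    D[i] <- mean_log_spectrum(sb$d, spec$epsilon)
    cur <- sb$a
  }
  c(RA = sum(diff(A)), RH = sum(diff(H)), RV = sum(diff(V)), RD = sum(diff(D)))
}
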