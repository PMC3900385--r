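#' Sine-taper multitaper spectral estimate
#'
#' Multitaper PSD using the sine-taper family
#' `w_k(t) = sqrt(2/(N+1)) sin(pi k t/(N+1))`, averaged over `n_tapers`
#' tapers. Sine tapers have unit energy, so the one-sided PSD is
#' `2 dt |FFT|^2` averaged over tapers. Input columns are treated as
#' independent trials; a PSD column is returned per trial.
#'
#' @param x numeric vector or matrix (samples x trials)
#' @param dt sample interval (s)
#' @param n_tapers number of sine tapers
#' @param demean subtract each column's mean first
#' @return list: `freq` (Hz, length `floor(N/2) + 1`) and `psd`
#'   (matrix, frequencies x trials)
#' @export
mt_spectrum <- function(x, dt, n_tapers = 5, demean = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (demean) x <- sweep(x, 2, colMeans(x))
  tapers <- mt_tapers(n, n_tapers)
  nf <- floor(n / 2) + 1
  psd <- matrix(0, nf, ncol(x))
  for (k in seq_len(n_tapers)) {
    xf <- stats::mvfft(x * tapers[, k])
    psd <- psd + Mod(xf[seq_len(nf), , drop = FALSE])^2
  }
  psd <- psd / n_tapers * dt
  psd[2:(nf - 1), ] <- 2 * psd[2:(nf - 1), ]  # one-sided
  list(freq = (seq_len(nf) - 1) / (n * dt), psd = psd,
       n_tapers = n_tapers)
}

mt_tapers <- function(n, k) {
  outer(seq_len(n), seq_len(k), function(t, j) {
    sqrt(2 / (n + 1)) * sin(pi * j * t / (n + 1))
  })
}

# Tapered FFTs on the full (two-sided) frequency grid: returns a complex
# array [freq, taper, trial] for cross-spectral averaging.
mt_fft <- function(x, n_tapers = 5, demean = TRUE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (demean) x <- sweep(x, 2, colMeans(x))
  tapers <- mt_tapers(n, n_tapers)
  out <- array(0i, dim = c(n, n_tapers, ncol(x)))
  for (k in seq_len(n_tapers)) {
    out[, k, ] <- stats::mvfft(x * tapers[, k])
  }
  out
}

#' Trapezoidal integral over a frequency band
#'
#' @param freq frequency grid (Hz, increasing)
#' @param y integrand samples
#' @param band two-element band limits (Hz); must lie within the grid
#' @return the integral
#' @export
band_integral <- function(freq, y, band = c(0, 300)) {
  stopifnot(length(band) == 2, band[1] < band[2])
  if (band[1] < min(freq) - 1e-9 || band[2] > max(freq) + 1e-9) {
    stop("integration band outside the frequency grid", call. = FALSE)
  }
  sel <- freq >= band[1] & freq <= band[2]
  f <- freq[sel]
  v <- y[sel]
  sum(diff(f) * (v[-1] + v[-length(v)]) / 2)
}
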