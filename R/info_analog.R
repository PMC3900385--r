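#' Split frozen-noise trials into signal and noise
#'
#' The signal is the pointwise mean across trials of an identical
#' (frozen) stimulus; the noise in each trial is the residual from that
#' mean.
#'
#' @param trials numeric matrix (samples x trials) or list of equal-length
#'   numeric vectors / `simulation_result`s
#' @return list: `signal` (vector), `noise` (matrix samples x trials)
#' @export
signal_noise_split <- function(trials) {
  m <- as_trial_matrix(trials)
  if (ncol(m) < 2) stop("need at least 2 trials", call. = FALSE)
  signal <- rowMeans(m)
  list(signal = signal, noise = m - signal)
}

as_trial_matrix <- function(trials) {
  if (is.matrix(trials)) return(trials)
  if (is.list(trials)) {
    vecs <- lapply(trials, function(x) {
      if (inherits(x, "simulation_result")) x$v
      else if (inherits(x, "current_trace")) x$values
      else as.numeric(x)
    })
    len <- unique(lengths(vecs))
    if (length(len) != 1) stop("trials have unequal lengths", call. = FALSE)
    return(do.call(cbind, vecs))
  }
  as.matrix(trials)
}

#' Signal and noise spectra of frozen-noise trials
#'
#' Multitaper PSD of the trial-mean (signal) and the trial-averaged PSD of
#' the residuals (noise), with their ratio as the per-frequency SNR.
#'
#' @inheritParams signal_noise_split
#' @param dt sample interval (s)
#' @param n_tapers sine tapers per trace
#' @return a `spectral_estimate`: tibble-backed list with `freq`,
#'   `signal_psd`, `noise_psd`, `snr`, plus estimator metadata
#' @export
spectral_estimate <- function(trials, dt, n_tapers = 5) {
  sp <- signal_noise_split(trials)
  sig <- mt_spectrum(sp$signal, dt, n_tapers)
  noi <- mt_spectrum(sp$noise, dt, n_tapers)
  noise_psd <- rowMeans(noi$psd)
  structure(
    list(freq = sig$freq,
         signal_psd = as.numeric(sig$psd),
         noise_psd = noise_psd,
         snr = as.numeric(sig$psd) / pmax(noise_psd, .Machine$double.xmin),
         n_tapers = n_tapers, n_trials = ncol(sp$noise), dt = dt),
    class = "spectral_estimate"
  )
}

#' @export
print.spectral_estimate <- function(x, ...) {
  cat(sprintf(
    "<spectral_estimate> %d frequencies (0-%.0f Hz), %d trials, %d tapers\n",
    length(x$freq), max(x$freq), x$n_trials, x$n_tapers))
  invisible(x)
}

#' Gaussian-channel information rate
#'
#' Shannon upper bound for an additive Gaussian channel:
#' `integral of log2(1 + SNR(f)) df` over `band`, evaluated by the
#' trapezoidal rule.
#'
#' @param spec a `spectral_estimate`, or a list with `freq` and `snr`
#' @param band integration band (Hz)
#' @return information rate (bits/s)
#' @export
gaussian_info <- function(spec, band = c(0, 300)) {
  band_integral(spec$freq, log2(1 + spec$snr), band)
}

#' Analogue information pipeline for frozen-noise voltage responses
#'
#' Composition of the signal/noise split, multitaper spectral estimation
#' and the Gaussian-channel bound.
#'
#' @inheritParams spectral_estimate
#' @param band integration band (Hz)
#' @return an `analog_info` object: `info` (bits/s), the underlying
#'   `spectral_estimate`, and the band
#' @export
analog_info <- function(trials, dt, band = c(0, 300), n_tapers = 5) {
  spec <- spectral_estimate(trials, dt, n_tapers)
  structure(
    list(info = gaussian_info(spec, band), spectrum = spec, band = band),
    class = "analog_info"
  )
}

#' @export
print.analog_info <- function(x, ...) {
  cat(sprintf("<analog_info> %.1f bits/s over %g-%g Hz (%d trials)\n",
              x$info, x$band[1], x$band[2], x$spectrum$n_trials))
  invisible(x)
}
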