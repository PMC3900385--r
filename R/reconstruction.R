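#' Fit forward and reverse Wiener filters
#'
#' Frequency-domain optimal linear filters between stimulus and response,
#' estimated from the training portion of a trial set: the forward filter
#' is the stimulus-response cross-spectrum normalised by the stimulus
#' power spectrum, the reverse filter the same cross-spectrum normalised
#' by the response power spectrum. Cross- and auto-spectra are averaged
#' over training trials and sine tapers. Cross-validation uses the first
#' `split` fraction of trial indices for training.
#'
#' @param stimuli list of [current_trace()] or numeric vectors (one per
#'   trial)
#' @param responses list of numeric vectors: voltage traces or 0/1 spike
#'   indicator vectors at the same resolution
#' @param dt sample interval (s)
#' @param split training fraction of trials (first `split` of indices)
#' @param n_tapers sine tapers for the spectral averages
#' @return a `wiener_filters` object: complex `forward` and `reverse`
#'   transfer functions on the full FFT grid, `freq` (one-sided grid, Hz),
#'   `train_idx`, `test_idx`, `dt`
#' @export
fit_reverse_filter <- function(stimuli, responses, dt, split = 0.65,
                               n_tapers = 5) {
  s_mat <- as_trial_matrix(stimuli)
  r_mat <- as_trial_matrix(responses)
  stopifnot(ncol(s_mat) == ncol(r_mat), nrow(s_mat) == nrow(r_mat))
  n_trials <- ncol(s_mat)
  n_train <- max(1, floor(split * n_trials))
  if (n_train < 3) stop("need at least 3 training trials", call. = FALSE)
  train_idx <- seq_len(n_train)
  test_idx <- setdiff(seq_len(n_trials), train_idx)

  sf <- mt_fft(s_mat[, train_idx, drop = FALSE], n_tapers)
  rf <- mt_fft(r_mat[, train_idx, drop = FALSE], n_tapers)
  csr <- apply(sf * Conj(rf), 1, mean)       # <S R*>
  crs <- Conj(csr)                           # <R S*>
  pss <- apply(Mod(sf)^2, 1, mean)
  prr <- apply(Mod(rf)^2, 1, mean)
  if (all(prr < .Machine$double.eps)) {
    stop("zero response power: cannot fit a reverse filter", call. = FALSE)
  }
  n <- nrow(s_mat)
  structure(
    list(forward = crs / pmax(pss, .Machine$double.xmin),
         reverse = csr / pmax(prr, .Machine$double.xmin),
         freq = (0:(floor(n / 2))) / (n * dt),
         train_idx = train_idx, test_idx = test_idx,
         dt = dt, n_tapers = n_tapers),
    class = "wiener_filters"
  )
}

#' @export
print.wiener_filters <- function(x, ...) {
  cat(sprintf("<wiener_filters> %d training / %d test trials, dt = %g s\n",
              length(x$train_idx), length(x$test_idx), x$dt))
  invisible(x)
}

#' Reconstruct the stimulus and score the reconstruction
#'
#' Applies the reverse filter to the test responses to obtain stimulus
#' estimates, then scores them by (i) the stimulus-response coherence
#' `gamma^2(f)` averaged over test trials and tapers, (ii) the normalised
#' RMS error between true and reconstructed stimulus (normalised by the
#' stimulus SD about its mean), and (iii) the coherence information rate
#' `-integral log2(1 - gamma^2) df` over `band` (trapezoidal).
#'
#' @param filters a [fit_reverse_filter()] result
#' @param stimuli,responses the full trial set the filters were fitted on
#'   (test trials are selected by `filters$test_idx`)
#' @param band integration band (Hz)
#' @return a `reconstruction_result`: `coherence` tibble (`freq`,
#'   `gamma2`), `nrmse`, `coherence_info` (bits/s), and the reconstructed
#'   test stimuli (matrix)
#' @export
reconstruct_and_score <- function(filters, stimuli, responses,
                                  band = c(0, 300)) {
  stopifnot(inherits(filters, "wiener_filters"))
  s_mat <- as_trial_matrix(stimuli)
  r_mat <- as_trial_matrix(responses)
  idx <- filters$test_idx
  if (length(idx) < 2) stop("need at least 2 test trials", call. = FALSE)
  s_test <- sweep(s_mat[, idx, drop = FALSE], 2,
                  colMeans(s_mat[, idx, drop = FALSE]))
  r_test <- sweep(r_mat[, idx, drop = FALSE], 2,
                  colMeans(r_mat[, idx, drop = FALSE]))
  n <- nrow(s_test)

  # time-domain reconstruction via the reverse filter
  s_hat <- apply(r_test, 2, function(r) {
    Re(stats::fft(filters$reverse * stats::fft(r), inverse = TRUE)) / n
  })

  # coherence between true and reconstructed stimulus on the test set
  sf <- mt_fft(s_test, filters$n_tapers)
  hf <- mt_fft(s_hat, filters$n_tapers)
  csh <- apply(sf * Conj(hf), 1, mean)
  pss <- apply(Mod(sf)^2, 1, mean)
  phh <- apply(Mod(hf)^2, 1, mean)
  gamma2 <- Mod(csh)^2 / pmax(pss * phh, .Machine$double.xmin)
  nf <- floor(n / 2) + 1
  gamma2 <- gamma2[seq_len(nf)]
  if (any(gamma2 > 1)) {
    warning("coherence numerically above 1; clipping")
    gamma2 <- pmin(gamma2, 1 - 1e-12)
  }
  freq <- (seq_len(nf) - 1) / (n * filters$dt)

  nrmse <- mean(vapply(seq_along(idx), function(j) {
    sqrt(mean((s_test[, j] - s_hat[, j])^2)) / stats::sd(s_test[, j])
  }, numeric(1)))

  info <- -band_integral(freq, log2(pmax(1 - gamma2, 1e-300)), band)

  structure(
    list(coherence = tibble::tibble(freq = freq, gamma2 = gamma2),
         nrmse = nrmse, coherence_info = info,
         reconstructed = s_hat, band = band,
         n_test = length(idx)),
    class = "reconstruction_result"
  )
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf(
    "<reconstruction_result> coherence info %.1f bits/s, nRMSE %.3f (%d test trials)\n",
    x$coherence_info, x$nrmse, x$n_test))
  invisible(x)
}

#' End-to-end Wiener reconstruction pipeline
#'
#' Convenience wrapper: fit the filters on the first 65% of trials and
#' score on the remainder.
#'
#' @inheritParams fit_reverse_filter
#' @inheritParams reconstruct_and_score
#' @return a `reconstruction_result`
#' @export
wiener_pipeline <- function(stimuli, responses, dt, split = 0.65,
                            band = c(0, 300), n_tapers = 5) {
  filt <- fit_reverse_filter(stimuli, responses, dt, split, n_tapers)
  reconstruct_and_score(filt, stimuli, responses, band)
}
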