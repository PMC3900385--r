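#' Stimulus configuration
#'
#' Parameters of the band-limited Gaussian white-noise current stimulus:
#' a broadband Gaussian sequence low-pass filtered at `cutoff` Hz by an
#' order-`filter_order` Butterworth filter (realised as second-order
#' sections), then rescaled to the requested mean and SD.
#'
#' @param mean stimulus mean (uA/cm^2)
#' @param sd stimulus standard deviation (uA/cm^2)
#' @param cutoff low-pass cutoff (Hz)
#' @param filter_order Butterworth order
#' @param duration trial length (s)
#' @param dt sample interval (s)
#' @param n_trials number of trials
#' @param frozen if `TRUE` every trial is the identical realisation
#' @param snr extrinsic signal-to-noise ratio Omega, or `NULL` for no
#'   extrinsic noise
#' @param seed master seed; per-trial child seeds derive from it
#' @return a `stimulus_config` list
#' @export
stimulus_config <- function(mean = 0, sd = 1, cutoff = 300,
                            filter_order = 40, duration = 1, dt = 1e-5,
                            n_trials = 60, frozen = FALSE, snr = NULL,
                            seed = 1L) {
  stopifnot(sd >= 0, duration > 0, dt > 0, n_trials >= 1)
  if (cutoff >= 1 / (2 * dt)) {
    stop("`cutoff` must be below the Nyquist frequency 1/(2 dt)",
         call. = FALSE)
  }
  if (!is.null(snr) && snr <= 0) stop("`snr` must be positive", call. = FALSE)
  structure(
    list(mean = mean, sd = sd, cutoff = cutoff, filter_order = filter_order,
         duration = duration, dt = dt, n_trials = as.integer(n_trials),
         frozen = frozen, snr = snr, seed = as.integer(seed)),
    class = "stimulus_config"
  )
}

#' A uniformly sampled current trace
#'
#' Lightweight carrier for current signals: a numeric vector of samples
#' (uA/cm^2) with sample interval `dt` (s) and optional metadata.
#'
#' @param values numeric samples (uA/cm^2)
#' @param dt sample interval (s)
#' @param meta optional list of provenance metadata
#' @export
current_trace <- function(values, dt, meta = list()) {
  stopifnot(is.numeric(values), all(is.finite(values)), dt > 0)
  structure(list(values = values, dt = dt, meta = meta),
            class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "<current_trace> %d samples @ dt = %g s (%.3g s), mean %.3g, sd %.3g uA/cm^2\n",
    length(x$values), x$dt, length(x$values) * x$dt,
    mean(x$values), stats::sd(x$values)))
  invisible(x)
}

# Second-order sections of an analog-prototype Butterworth low-pass,
# discretised by the bilinear transform. Poles come from the closed form
# exp(i*pi*(2k + n - 1)/(2n)); designing per conjugate pair keeps order-40
# filters numerically stable where a single transfer function would not be.
butter_sos <- function(order, cutoff, fs) {
  stopifnot(order %% 2 == 0, cutoff > 0, cutoff < fs / 2)
  n <- order
  wc <- 2 * fs * tan(pi * cutoff / fs)  # pre-warped analog cutoff
  k2 <- 2 * fs
  sections <- lapply(seq_len(n / 2), function(k) {
    theta <- pi * (2 * k + n - 1) / (2 * n)
    zeta <- -cos(theta)  # damping ratio of the conjugate pole pair
    a0 <- k2^2 + 2 * zeta * wc * k2 + wc^2
    list(
      b = wc^2 * c(1, 2, 1) / a0,
      a = c(1, (2 * wc^2 - 2 * k2^2) / a0, (k2^2 - 2 * zeta * wc * k2 + wc^2) / a0)
    )
  })
  sections
}

apply_sos <- function(x, sections) {
  for (s in sections) {
    x <- as.numeric(signal::filter(s$b, s$a, x))
  }
  x
}

# Deterministic per-trial child seeds below 2^31.
child_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(seed)
  force(code)
}

#' Band-limited Gaussian white-noise stimuli
#'
#' Generates one [current_trace()] per trial: oversampled Gaussian white
#' noise filtered by the configured Butterworth low-pass (second-order
#' sections, causal, with a discarded lead-in to remove the filter
#' transient), then rescaled to exactly the configured sample mean and SD.
#' Frozen configurations replicate a single realisation across trials.
#'
#' @param config a [stimulus_config()]
#' @return list of [current_trace()] objects, length `config$n_trials`
#' @export
band_limited_noise <- function(config) {
  stopifnot(inherits(config, "stimulus_config"))
  n <- round(config$duration / config$dt)
  fs <- 1 / config$dt
  lead <- round(0.05 / config$dt)  # 50 ms lead-in absorbs filter transient
  sections <- butter_sos(config$filter_order, config$cutoff, fs)

  one_trial <- function(seed) {
    if (config$sd == 0) {
      return(current_trace(rep(config$mean, n), config$dt,
                           meta = list(config = config, seed = seed)))
    }
    x <- with_seed(seed, stats::rnorm(n + lead))
    x <- apply_sos(x, sections)[(lead + 1):(lead + n)]
    x <- (x - mean(x)) / stats::sd(x) * config$sd + config$mean
    current_trace(x, config$dt, meta = list(config = config, seed = seed))
  }

  if (config$frozen) {
    tr <- one_trial(child_seeds(config$seed, 1)[1])
    out <- replicate(config$n_trials, tr, simplify = FALSE)
  } else {
    seeds <- child_seeds(config$seed, config$n_trials)
    out <- lapply(seeds, one_trial)
  }
  if (!is.null(config$snr)) {
    noise_seeds <- child_seeds(config$seed + 1L, config$n_trials)
    out <- purrr::map2(out, noise_seeds, function(tr, s) {
      add_extrinsic_noise(tr, snr = config$snr, seed = s,
                          signal_sd = config$sd)
    })
  }
  out
}

#' Add broadband extrinsic noise at a fixed signal-to-noise ratio
#'
#' Adds zero-mean unfiltered Gaussian white noise with variance
#' `signal_sd^2 / snr` to a current trace. The noise is regenerated per
#' call (per trial): it is extrinsic, not part of a frozen stimulus.
#'
#' @param trace a [current_trace()]
#' @param snr signal-to-noise ratio Omega (> 0); `Inf` returns the trace
#'   unchanged
#' @param seed RNG seed for the noise
#' @param signal_sd SD of the underlying signal (defaults to the trace's
#'   sample SD)
#' @return a [current_trace()]
#' @export
add_extrinsic_noise <- function(trace, snr, seed = 1L,
                                signal_sd = stats::sd(trace$values)) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.infinite(snr)) return(trace)
  if (snr <= 0) stop("`snr` must be positive", call. = FALSE)
  noise <- with_seed(seed, stats::rnorm(length(trace$values),
                                        sd = signal_sd / sqrt(snr)))
  current_trace(trace$values + noise, trace$dt,
                meta = c(trace$meta, list(snr = snr, noise_seed = seed)))
}

#' Welch-style averaged power spectral density of stimulus trials
#'
#' Diagnostic PSD (periodograms averaged over trials and tapers) used to
#' verify the stimulus passband. One-sided, units (uA/cm^2)^2 / Hz.
#'
#' @param traces list of [current_trace()]
#' @param n_tapers sine tapers per trial
#' @return tibble with columns `freq` (Hz) and `psd`
#' @export
stimulus_psd <- function(traces, n_tapers = 5) {
  m <- vapply(traces, function(tr) tr$values - mean(tr$values),
              numeric(length(traces[[1]]$values)))
  sp <- mt_spectrum(m, dt = traces[[1]]$dt, n_tapers = n_tapers)
  tibble::tibble(freq = sp$freq, psd = rowMeans(sp$psd))
}
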