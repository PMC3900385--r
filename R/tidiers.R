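#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.entropy_estimate <- function(x, ...) x$by_k

#' @export
glance.entropy_estimate <- function(x, ...) {
  tibble::tibble(
    total_entropy_rate = x$total_entropy_rate,
    noise_entropy_rate = x$noise_entropy_rate,
    info_rate = x$info_rate,
    info_rate_raw = x$info_rate_raw,
    fit_rms_total = x$fit_total$rms,
    fit_rms_noise = x$fit_noise$rms,
    n_frozen = x$n_frozen, n_unfrozen = x$n_unfrozen
  )
}

#' @export
tidy.analog_info <- function(x, ...) {
  tibble::tibble(
    freq = x$spectrum$freq,
    signal_psd = x$spectrum$signal_psd,
    noise_psd = x$spectrum$noise_psd,
    snr = x$spectrum$snr
  )
}

#' @export
glance.analog_info <- function(x, ...) {
  tibble::tibble(info_rate = x$info, band_lo = x$band[1],
                 band_hi = x$band[2], n_trials = x$spectrum$n_trials,
                 n_tapers = x$spectrum$n_tapers)
}

#' @export
tidy.reconstruction_result <- function(x, ...) x$coherence

#' @export
glance.reconstruction_result <- function(x, ...) {
  tibble::tibble(coherence_info = x$coherence_info, nrmse = x$nrmse,
                 band_lo = x$band[1], band_hi = x$band[2],
                 n_test = x$n_test)
}

#' @export
tidy.energy_report <- function(x, ...) {
  tibble::tibble(trial = seq_along(x$atp_by_trial),
                 atp_per_second = x$atp_by_trial)
}

#' @export
glance.energy_report <- function(x, ...) {
  tibble::tibble(atp_per_second = x$atp_per_second,
                 info_rate = x$info_rate, efficiency = x$efficiency)
}

#' @export
autoplot.simulation_result <- function(object, ...) {
  df <- tibble::tibble(
    time = (seq_along(object$v) - 1) * object$dt,
    v = object$v
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "membrane potential (mV)")
}

#' @export
autoplot.analog_info <- function(object, ...) {
  df <- tidy.analog_info(object) |>
    tidyr::pivot_longer(c("signal_psd", "noise_psd"),
                        names_to = "component", values_to = "psd")
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$psd,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::coord_cartesian(xlim = object$band) +
    ggplot2::labs(x = "frequency (Hz)", y = "PSD (mV^2/Hz)",
                  title = sprintf("Gaussian-channel bound: %.0f bits/s",
                                  object$info))
}

#' @export
autoplot.entropy_estimate <- function(object, ...) {
  df <- object$by_k |>
    tidyr::pivot_longer(c("total_rate", "noise_rate"),
                        names_to = "entropy", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(.data$inv_t, .data$rate,
                                   colour = .data$entropy)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$fit_total$intercept,
                         slope = object$fit_total$slope,
                         linetype = 2) +
    ggplot2::geom_abline(intercept = object$fit_noise$intercept,
                         slope = object$fit_noise$slope,
                         linetype = 3) +
    ggplot2::labs(x = "1/T (1/s)", y = "entropy rate (bits/s)")
}

#' @export
autoplot.reconstruction_result <- function(object, ...) {
  ggplot2::ggplot(object$coherence,
                  ggplot2::aes(.data$freq, .data$gamma2)) +
    ggplot2::geom_line() +
    ggplot2::coord_cartesian(xlim = object$band, ylim = c(0, 1)) +
    ggplot2::labs(x = "frequency (Hz)", y = expression(gamma^2),
                  title = sprintf("coherence info: %.0f bits/s, nRMSE %.2f",
                                  object$coherence_info, object$nrmse))
}

#' Spike raster of a trial set
#'
#' @param trains list of spike-time vectors (s)
#' @return a ggplot
#' @export
plot_raster <- function(trains) {
  df <- purrr::imap_dfr(trains, function(sp, i) {
    tibble::tibble(trial = i, time = sp)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$trial)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = "time (s)", y = "trial")
}
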