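#' Deterministic test fixtures with closed-form expectations
#'
#' Generates small analytic fixtures so every estimator can be tested
#' without running the full simulator. Each fixture carries the data and
#' the closed-form expected values.
#'
#' Available fixtures:
#' \describe{
#'   \item{`two_state_channel`}{open/close scheme with rates alpha, beta;
#'     expected equilibrium open fraction `alpha/(alpha+beta)`.}
#'   \item{`bernoulli_train`}{iid 0/1 letter sequences at rate `p`;
#'     expected entropy `H(p)` bits/letter.}
#'   \item{`linear_system`}{white signal plus independent white noise at
#'     power ratio `snr`; expected coherence `snr/(1+snr)` and
#'     Gaussian-channel integrand `log2(1+snr)` flat in frequency.}
#'   \item{`constant_current`}{constant current trace; expected ATP/s from
#'     exact stoichiometry.}
#'   \item{`triangle_spikes`}{flat baseline with triangular 100 mV
#'     transients; expected spike times.}
#' }
#'
#' @param name fixture name
#' @param params named list of fixture parameters (see defaults in code)
#' @param seed RNG seed
#' @return list with fixture `data` and `expected` values
#' @export
make_fixture <- function(name = c("two_state_channel", "bernoulli_train",
                                  "linear_system", "constant_current",
                                  "triangle_spikes"),
                         params = list(), seed = 1L) {
  name <- match.arg(name)
  p <- function(key, default) if (!is.null(params[[key]])) params[[key]] else default

  switch(name,
    two_state_channel = {
      alpha <- p("alpha", 1)
      beta <- p("beta", 1)
      n <- p("n_channels", 1000L)
      list(
        data = list(counts = c(closed = n, open = 0L),
                    src = c(0L, 1L), dst = c(1L, 0L),
                    rates = c(alpha, beta)),
        expected = list(open_fraction = alpha / (alpha + beta))
      )
    },
    bernoulli_train = {
      prob <- p("p", 0.5)
      n_trials <- p("n_trials", 10L)
      n_bins <- p("n_bins", 1000L)
      letters <- with_seed(seed, {
        lapply(seq_len(n_trials), function(i) {
          as.integer(stats::runif(n_bins) < prob)
        })
      })
      h <- if (prob %in% c(0, 1)) 0 else {
        -prob * log2(prob) - (1 - prob) * log2(1 - prob)
      }
      list(data = list(letters = letters, n_bins = n_bins),
           expected = list(bits_per_letter = h))
    },
    linear_system = {
      snr <- p("snr", 1)
      n <- p("n", 20000L)
      n_trials <- p("n_trials", 20L)
      dt <- p("dt", 1e-3)
      sim <- with_seed(seed, {
        s <- matrix(stats::rnorm(n * n_trials), n)
        r <- s + matrix(stats::rnorm(n * n_trials, sd = 1 / sqrt(snr)), n)
        list(s = s, r = r)
      })
      list(data = list(stimuli = sim$s, responses = sim$r, dt = dt),
           expected = list(gamma2 = snr / (1 + snr),
                           info_per_hz = log2(1 + snr)))
    },
    constant_current = {
      amp <- p("amp", 1)        # uA/cm^2
      area <- p("area", 100)    # um^2
      dur <- p("duration", 1)
      dt <- p("dt", 1e-5)
      i_k <- rep(amp, round(dur / dt))
      q <- amp * 1e-6 * area * 1e-8 * dur
      list(data = list(i_k = i_k, dt = dt, area = area),
           expected = list(atp_per_s = q / (2 * .elementary_charge) / dur))
    },
    triangle_spikes = {
      n_spikes <- p("n_spikes", 3L)
      gap_ms <- p("gap_ms", 20)
      dt <- p("dt", 1e-5)
      baseline <- p("baseline", -65)
      dur <- (n_spikes + 1) * gap_ms / 1000
      v <- rep(baseline, round(dur / dt))
      half <- round(0.5e-3 / dt)  # 0.5 ms rise and fall
      onsets <- (seq_len(n_spikes) * gap_ms / 1000)
      for (t0 in onsets) {
        i0 <- round(t0 / dt)
        ramp <- seq(baseline, baseline + 100, length.out = half)
        v[i0 + seq_len(half)] <- ramp
        v[i0 + half + seq_len(half)] <- rev(ramp)
      }
      list(data = list(v = v, dt = dt),
           expected = list(spike_times = onsets, baseline = baseline))
    }
  )
}
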