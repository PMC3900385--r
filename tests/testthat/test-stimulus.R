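test_that("degenerate and frozen stimuli behave as defined", {
  cfg0 <- stimulus_config(mean = 5, sd = 0, n_trials = 2, seed = 3)
  tr <- band_limited_noise(cfg0)
  expect_true(all(tr[[1]]$values == 5))

  cfgf <- stimulus_config(mean = 0, sd = 5, n_trials = 3, frozen = TRUE,
                          seed = 4)
  fr <- band_limited_noise(cfgf)
  expect_identical(fr[[1]]$values, fr[[2]]$values)
  expect_identical(fr[[2]]$values, fr[[3]]$values)

  cfgu <- stimulus_config(mean = 0, sd = 5, n_trials = 2, seed = 4)
  un <- band_limited_noise(cfgu)
  expect_false(identical(un[[1]]$values, un[[2]]$values))
})

test_that("generated stimuli hit the configured moments and reproduce under a seed", {
  cfg <- stimulus_config(mean = 3, sd = 7, n_trials = 4, seed = 11)
  tr <- band_limited_noise(cfg)
  for (t in tr) {
    expect_equal(mean(t$values), 3, tolerance = 1e-9)
    expect_equal(stats::sd(t$values), 7, tolerance = 1e-9)
    expect_length(t$values, 100000)
  }
  tr2 <- band_limited_noise(cfg)
  expect_identical(tr[[2]]$values, tr2[[2]]$values)
  expect_error(stimulus_config(cutoff = 6e4, dt = 1e-5), "Nyquist")
})

test_that("stimulus PSD is flat in the passband and strongly attenuated above cutoff", {
  cfg <- stimulus_config(mean = 0, sd = 5, cutoff = 300, n_trials = 60,
                         seed = 21)
  psd <- stimulus_psd(band_limited_noise(cfg))
  passband <- psd$psd[psd$freq >= 10 & psd$freq <= 250]
  ref <- stats::median(passband)
  # flat within +-3 dB over 10-250 Hz
  expect_lt(max(10 * log10(passband / ref)), 3)
  expect_gt(min(10 * log10(passband / ref)), -3)
  # >= 60 dB down at 400 Hz (>1.2x cutoff)
  stop_level <- mean(psd$psd[psd$freq >= 395 & psd$freq <= 405])
  expect_lt(10 * log10(stop_level / ref), -60)
})

test_that("extrinsic noise has variance sigma_signal^2 / Omega and is per-trial", {
  base <- current_trace(rep(0, 1e6), 1e-5)
  out <- add_extrinsic_noise(base, snr = 1, seed = 5, signal_sd = 5)
  added <- out$values - base$values
  expect_equal(stats::var(added), 25, tolerance = 0.05 * 25)
  expect_equal(mean(added), 0, tolerance = 3 * 5 / sqrt(1e6))

  # Omega = 2 vs Omega = 20: noise power ratio 10:1
  n2 <- add_extrinsic_noise(base, snr = 2, seed = 6, signal_sd = 5)$values
  n20 <- add_extrinsic_noise(base, snr = 20, seed = 6, signal_sd = 5)$values
  expect_equal(stats::var(n2) / stats::var(n20), 10, tolerance = 0.05 * 10)

  expect_identical(add_extrinsic_noise(base, snr = Inf)$values, base$values)
  expect_error(add_extrinsic_noise(base, snr = 0), "positive")

  # frozen stimulus with extrinsic noise: signals identical, noise not
  cfg <- stimulus_config(mean = 0, sd = 5, n_trials = 2, frozen = TRUE,
                         snr = 2, seed = 9)
  tr <- band_limited_noise(cfg)
  expect_false(identical(tr[[1]]$values, tr[[2]]$values))
})
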