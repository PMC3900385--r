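make_white_trials <- function(n, n_trials, seed, noise_sd = 0) {
  withr::with_seed(seed, {
    s <- matrix(stats::rnorm(n * n_trials), n)
    r <- s + if (noise_sd > 0) {
      matrix(stats::rnorm(n * n_trials, sd = noise_sd), n)
    } else 0
    list(s = s, r = r)
  })
}

test_that("identity and delayed responses give the expected filters", {
  d <- make_white_trials(4000, 10, seed = 61)
  filt <- fit_reverse_filter(d$s, d$s, dt = 1e-3)
  expect_equal(Mod(filt$reverse), rep(1, 4000), tolerance = 1e-9)

  # delay by tau: |G| ~ 1, phase = 2 pi f tau (tapering makes the
  # circular-shift relation approximate rather than exact)
  tau_idx <- 7
  r_del <- rbind(d$s[(4000 - tau_idx + 1):4000, ], d$s[1:(4000 - tau_idx), ])
  filt_d <- fit_reverse_filter(d$s, r_del, dt = 1e-3)
  expect_equal(Mod(filt_d$reverse), rep(1, 4000), tolerance = 0.01)
  k <- 11  # an arbitrary positive-frequency bin (0-based index 10)
  expected_phase <- 2 * pi * (k - 1) * tau_idx / 4000
  expect_equal(Arg(filt_d$reverse[k]), expected_phase, tolerance = 0.01)
})

test_that("equal-power additive noise halves the filter and the coherence", {
  fx <- make_fixture("linear_system", params = list(snr = 1), seed = 62)
  filt <- fit_reverse_filter(fx$data$stimuli, fx$data$responses,
                             dt = fx$data$dt)
  in_band <- filt$freq > 5 & filt$freq < 450
  expect_equal(mean(Mod(filt$reverse[seq_along(filt$freq)][in_band])),
               0.5, tolerance = 0.05)

  rec <- reconstruct_and_score(filt, fx$data$stimuli, fx$data$responses,
                               band = c(0, 300))
  sel <- rec$coherence$freq > 5 & rec$coherence$freq < 300
  expect_equal(mean(rec$coherence$gamma2[sel]), fx$expected$gamma2,
               tolerance = 0.05)
  # -integral log2(1 - 1/2) over 300 Hz = 300 bits/s
  expect_equal(rec$coherence_info, 300, tolerance = 0.05 * 300 + 15)
  # Wiener solution for SNR 1: nRMSE = sqrt(1 - P_S/(P_S+P_N)) ~ 0.707
  expect_equal(rec$nrmse, sqrt(0.5), tolerance = 0.05)
})

test_that("perfect and uninformative responses bound the scores", {
  d <- make_white_trials(4000, 10, seed = 63)
  rec_perfect <- suppressWarnings(
    wiener_pipeline(d$s, d$s, dt = 1e-3, band = c(0, 300)))
  expect_lt(rec_perfect$nrmse, 1e-6)
  expect_true(all(rec_perfect$coherence$gamma2 <= 1))

  withr::with_seed(64, r_junk <- matrix(stats::rnorm(4000 * 10), 4000))
  rec_junk <- wiener_pipeline(d$s, r_junk, dt = 1e-3, band = c(0, 300))
  sel <- rec_junk$coherence$freq <= 300
  expect_lt(mean(rec_junk$coherence$gamma2[sel]), 0.15)
  expect_lt(rec_junk$coherence_info, 60)
  expect_gt(rec_junk$nrmse, 0.9)
})

test_that("train/test split is disjoint and honours the 65-35 convention", {
  d <- make_white_trials(1000, 20, seed = 65)
  filt <- fit_reverse_filter(d$s, d$r, dt = 1e-3)
  expect_equal(filt$train_idx, 1:13)
  expect_equal(filt$test_idx, 14:20)
  expect_length(intersect(filt$train_idx, filt$test_idx), 0)
  expect_error(fit_reverse_filter(d$s[, 1:3], d$r[, 1:3], dt = 1e-3),
               "3 training")
})
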