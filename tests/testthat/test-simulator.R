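test_that("Gillespie selection follows the propensity ratios", {
  # single possible transition: always taken
  out <- withr::with_seed(1, analogspike:::gillespie_generic(
    c(1L, 0L), 0L, 1L, 1000, 1, 1L))
  expect_equal(out[1, ], c(0L, 1L))

  # zero total propensity: counts unchanged
  out0 <- analogspike:::gillespie_generic(c(5L, 0L), 1L, 0L, 2, 1, 3L)
  expect_true(all(out0[, 1] == 5L))

  # two competing transitions with a1 = 3 a2: selection ratio 3:1
  n <- 1e5L
  out2 <- withr::with_seed(2, analogspike:::gillespie_generic(
    c(n, 0L, 0L), c(0L, 0L), c(1L, 2L), c(3, 1), 50, 1L))
  expect_equal(out2[1, 1], 0L)  # all channels have left the source
  expect_equal(out2[1, 2] / n, 0.75, tolerance = 0.02)
})

test_that("K scheme at clamped voltage reaches the binomial equilibrium open fraction", {
  v <- -50
  sch <- channel_scheme("K")
  n_ch <- 1800L
  counts <- withr::with_seed(3, equilibrium_counts(sch, n_ch, v))
  n_windows <- 20000L  # 0.01 ms windows -> 200 ms
  traj <- withr::with_seed(4, gillespie_update(counts, sch, v, 0.01,
                                               n_windows))
  open_frac <- mean(traj[, "n4"]) / n_ch
  ss <- gating_steady_state(v)
  p <- ss$n_inf^4
  # +-3 SE with the effective sample count set by the n-gate correlation time
  n_eff <- n_windows * 0.01 / (2 * ss$tau_n)
  se <- sqrt(p * (1 - p) / n_ch) / sqrt(n_eff)
  expect_equal(open_frac, p, tolerance = max(3 * se / p, 1e-3))
})

test_that("graded model at rest stays near the resting potential", {
  m <- model_variant("graded")
  stim <- current_trace(rep(0, 5e4), 1e-5)  # 0.5 s
  sim <- simulate_trial(m, stim, seed = 5)
  rest <- resting_potential(na_present = FALSE)
  expect_lt(abs(mean(sim$v) - rest), 1)
  expect_lt(max(abs(sim$v - rest)), 5)
})

test_that("deterministic model fires repetitively with identical interspike intervals", {
  m <- model_config("deterministic", "deterministic")
  stim <- current_trace(rep(10, 1e5), 1e-5)
  sim <- simulate_trial(m, stim, seed = 1, burn_in = 0)
  sp <- detect_spikes(sim)
  expect_gt(length(sp), 30)
  isi <- diff(sp)[-1]  # drop the first interval (onset transient)
  expect_lt(max(isi) - min(isi), 3e-5)  # identical up to sampling jitter
})

test_that("per-step charge balance holds exactly under Euler integration", {
  p <- biophys_params()
  leak <- split_leak(p$g_leak, p$e_leak, p$e_k, p$e_na)
  for (variant in c("graded", "spiking")) {
    m <- model_variant(variant)
    stim <- current_trace(rep(2, 2000), 1e-5)
    sim <- simulate_trial(m, stim, seed = 6, burn_in = 0,
                          record_extra = TRUE)
    i_k_dr <- sim$i_k - leak$g_leak_k * (sim$v - p$e_k)
    i_leak <- p$g_leak * (sim$v - p$e_leak)
    i_tot <- sim$i_na + i_k_dr + i_leak
    dt_ms <- 1e-5 * 1000
    lhs <- p$membrane_capacitance * diff(sim$v)
    rhs <- (stim$values[-length(sim$v)] - i_tot[-length(sim$v)]) * dt_ms
    expect_equal(lhs, rhs, tolerance = 1e-9)
  }
})

test_that("channel counts are conserved and simulations are seed-deterministic", {
  m <- model_variant("spiking")
  cfg <- stimulus_config(mean = 1, sd = 10, duration = 0.1, n_trials = 1,
                         seed = 7)
  stim <- band_limited_noise(cfg)[[1]]
  s1 <- simulate_trial(m, stim, seed = 8, record_extra = TRUE)
  s2 <- simulate_trial(m, stim, seed = 8, record_extra = TRUE)
  expect_identical(s1$v, s2$v)
  s3 <- simulate_trial(m, stim, seed = 9)
  expect_false(identical(s1$v, s3$v))

  # occupancies stay in [0, N] and the open fraction is a valid proportion
  expect_true(all(s1$open_na >= 0 & s1$open_na <= 1))
  expect_true(all(s1$open_k >= 0 & s1$open_k <= 1))
  # voltage bounded in the physiological window (strong hyperpolarising
  # stimulus excursions can undershoot E_K through the leak)
  p <- m$params
  expect_true(all(s1$v > p$e_k - 25 & s1$v < p$e_na + 5))
})

test_that("large-N stochastic simulation converges to the deterministic trajectory", {
  # hyperpolarising mean keeps the trajectory safely sub-threshold, so
  # channel noise is the only difference from the ODE solution
  cfg <- stimulus_config(mean = -2, sd = 1, duration = 0.2, n_trials = 1,
                         seed = 10)
  stim <- band_limited_noise(cfg)[[1]]
  det <- simulate_trial(model_config("deterministic", "deterministic"),
                        stim, seed = 1)
  dev_at <- function(scale) {
    p <- biophys_params(n_na = 6000L * scale, n_k = 1800L * scale)
    m <- model_config("stochastic", "stochastic", params = p)
    sim <- simulate_trial(m, stim, seed = 11)
    sqrt(mean((sim$v - det$v)^2))
  }
  d4 <- dev_at(4L)
  d25 <- dev_at(25L)
  expect_lt(d25, d4 / 1.5)  # ~1/sqrt(N) shrinkage (factor 2.5 expected)
  expect_lt(d25, 0.3)       # close to the ODE oracle
})

test_that("spike detection handles flat, synthetic and dead-time cases", {
  expect_length(detect_spikes(rep(-65, 1000), 1e-5), 0)

  fx <- make_fixture("triangle_spikes")
  sp <- detect_spikes(fx$data$v, fx$data$dt)
  expect_length(sp, 3)
  expect_lt(max(abs(sp - fx$expected$spike_times)), 1e-3)

  # two crossings 1 ms apart collapse under a 2 ms dead time
  v <- rep(-65, 1000)
  v[c(100, 200)] <- 10
  sp2 <- detect_spikes(v, 1e-5, dead_time = 2)
  expect_length(sp2, 1)
})

test_that("holding-current search reaches sub-threshold targets", {
  g <- model_variant("graded")
  rest <- resting_potential(na_present = FALSE)
  h0 <- find_holding_current(g, rest, seed = 12)
  expect_lt(abs(h0$current), 0.5)
  h77 <- find_holding_current(g, -77, seed = 13)
  expect_lt(h77$current, 0)
  expect_equal(h77$achieved_mean_v, -77, tolerance = 0.5)
})
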