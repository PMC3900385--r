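test_that("pseudo-generator excision is identity without spikes and flattens isolated spikes", {
  v <- rep(-65, 5000)
  expect_identical(pseudo_generator(v, 1e-5), v)

  fx <- make_fixture("triangle_spikes", params = list(n_spikes = 1L))
  pg <- pseudo_generator(fx$data$v, fx$data$dt)
  # one spike on a constant baseline: line between equal endpoints
  expect_equal(pg, rep(fx$expected$baseline, length(pg)), tolerance = 1e-9)

  # a spike at the very edge is truncated to the trace boundary
  v_edge <- rep(-65, 1000)
  v_edge[995:1000] <- 30
  pg_edge <- pseudo_generator(v_edge, 1e-5, spikes = 995 * 1e-5)
  expect_length(pg_edge, 1000)
  expect_true(all(is.finite(pg_edge)))
})

test_that("footprint schemes respect gap, width and sharing constraints", {
  dt <- 1e-5
  m <- matrix(stats::rnorm(1e5 * 3), 1e5)
  for (sch in c("deterministic", "jittered", "random")) {
    plan <- footprint_plan(sch, n_per_second = 40, seed = 71)
    out <- insert_footprints(m, plan, dt)
    expect_length(out$positions, 3)
    for (pos in out$positions) {
      expect_length(pos, 40)
      expect_true(all(diff(sort(pos)) >= if (sch == "jittered") 6 else 10))
      expect_true(all(pos >= 0 & pos <= 1000 - 6))
    }
  }
  det <- insert_footprints(m, footprint_plan("deterministic", 20, seed = 72), dt)
  expect_identical(det$positions[[1]], det$positions[[2]])
  jit <- insert_footprints(m, footprint_plan("jittered", 20, seed = 72), dt)
  expect_identical(jit$positions[[1]], jit$positions[[2]])
  rnd <- insert_footprints(m, footprint_plan("random", 20, seed = 72), dt)
  expect_false(identical(rnd$positions[[1]], rnd$positions[[2]]))

  expect_error(insert_footprints(m, footprint_plan("random", 101), dt),
               "infeasible")
  expect_error(footprint_plan(min_gap = 3))  # gap below width
})

test_that("window interpolation is exact and stimulus interpolation matches positions", {
  x <- as.numeric(1:100)
  y <- analogspike:::interp_windows(x, 10L, 20L)
  expect_equal(y[10:20], seq(x[10], x[20], length.out = 11))
  expect_equal(y[-(10:20)], x[-(10:20)])
  # overlapping windows merge into one line
  y2 <- analogspike:::interp_windows(x, c(10L, 15L), c(20L, 30L))
  expect_equal(y2[10:30], seq(x[10], x[30], length.out = 21))

  m <- matrix(stats::rnorm(2e4 * 2), 2e4)
  expect_identical(interpolate_stimulus(m, list(numeric(0), numeric(0)),
                                        6, 1e-5), m)
  plan <- footprint_plan("random", 10, seed = 73)
  out <- insert_footprints(m, plan, 1e-5)
  sm <- interpolate_stimulus(m, out$positions, 6, 1e-5)
  # interpolated regions change, the rest is untouched
  expect_false(identical(sm, m))
  idx_start <- round(out$positions[[1]][1] / 1000 / 1e-5) + 1
  expect_identical(sm[seq_len(max(idx_start - 2, 1)), 1],
                   m[seq_len(max(idx_start - 2, 1)), 1])
})

test_that("random insertion lowers a trial-mean signal's power, deterministic keeps trials aligned", {
  dt <- 1e-5
  withr::with_seed(74, {
    base <- stats::rnorm(5e4)
    trials <- vapply(1:8, function(i) base + 0.05 * stats::rnorm(5e4),
                     numeric(5e4))
  })
  det <- insert_footprints(trials, footprint_plan("deterministic", 60,
                                                  seed = 75), dt)
  rnd <- insert_footprints(trials, footprint_plan("random", 60,
                                                  seed = 76), dt)
  # deterministic insertion leaves residual (noise) variance unchanged;
  # random insertion converts signal into trial-to-trial noise
  noise_var <- function(m) mean(apply(m - rowMeans(m), 2, stats::var))
  expect_equal(noise_var(det$traces), noise_var(trials), tolerance = 0.1)
  expect_gt(noise_var(rnd$traces), 5 * noise_var(trials))
})
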