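test_that("gating rates match the closed forms, including removable singularities", {
  expect_equal(gating_rates(-40)$alpha_m, 1.0)
  expect_equal(gating_rates(-55)$alpha_n, 0.1)
  expect_equal(gating_rates(-65)$beta_n, 0.125)
  # near-singularity continuity
  expect_equal(gating_rates(-40 + 1e-9)$alpha_m, 1.0, tolerance = 1e-6)
  expect_error(gating_rates(NaN), "finite")

  v_grid <- seq(-100, 60, by = 0.5)
  r <- gating_rates(v_grid)
  for (nm in names(r)) {
    expect_true(all(is.finite(r[[nm]])), info = nm)
    expect_true(all(r[[nm]] >= 0), info = nm)
  }
})

test_that("C++ and R gating rates agree", {
  for (v in c(-100, -77, -65, -55, -40.0000001, -40, -20, 0, 40)) {
    rr <- gating_rates(v)
    rc <- analogspike:::gating_rates_cpp(v)
    for (nm in names(rc)) {
      expect_equal(rc[[nm]], rr[[nm]], tolerance = 1e-12, info = nm)
    }
  }
})

test_that("channel schemes have the documented state/transition structure", {
  na <- channel_scheme("Na")
  k <- channel_scheme("K")
  expect_length(na$states, 8)
  expect_equal(nrow(na$transitions), 20)
  expect_length(k$states, 5)
  expect_equal(nrow(k$transitions), 8)
  expect_equal(length(na$states) + length(k$states), 13)
  expect_equal(nrow(na$transitions) + nrow(k$transitions), 28)
  expect_equal(na$conducting_state, "m3h1")
  expect_equal(k$conducting_state, "n4")

  # every transition's reverse exists; no orphan states
  for (sch in list(na, k)) {
    tr <- sch$transitions
    fwd <- paste(tr$from, tr$to)
    rev <- paste(tr$to, tr$from)
    expect_true(all(rev %in% fwd))
    expect_setequal(unique(c(tr$from, tr$to)), sch$states)
  }
  expect_error(channel_scheme("Ca"))
})

test_that("rate-matrix outflows equal the summed listed transitions", {
  for (kind in c("Na", "K")) {
    sch <- channel_scheme(kind)
    for (v in c(-90, -65, -30, 10)) {
      q <- rate_matrix(sch, v)
      r <- gating_rates(v)
      tr <- sch$transitions
      out_listed <- vapply(sch$states, function(s) {
        rows <- tr[tr$from == s, ]
        sum(vapply(seq_len(nrow(rows)), function(i) {
          rows$mult[i] * r[[paste0(rows$dir[i], "_", rows$gate[i])]]
        }, numeric(1)))
      }, numeric(1))
      expect_equal(-diag(q), out_listed, tolerance = 1e-12)
    }
  }
})

test_that("master-equation equilibria equal the binomial product closed forms", {
  for (v in c(-85, -70, -55, -30)) {
    ss <- gating_steady_state(v)
    pk <- scheme_equilibrium(channel_scheme("K"), v)
    expect_equal(unname(pk), stats::dbinom(0:4, 4, ss$n_inf),
                 tolerance = 1e-8)
    pna <- scheme_equilibrium(channel_scheme("Na"), v)
    expected <- as.vector(outer(stats::dbinom(0:3, 3, ss$m_inf),
                                c(1 - ss$h_inf, ss$h_inf)))
    expect_equal(unname(pna), expected, tolerance = 1e-8)
  }
})

test_that("biophys params enforce their invariants and resting potentials are sane", {
  p <- biophys_params()
  expect_s3_class(p, "biophys_params")
  expect_error(biophys_params(e_k = -40, e_leak = -54.4), "e_leak")
  expect_error(biophys_params(n_na = 0))
  rest <- resting_potential(p)
  expect_gt(rest, -70)
  expect_lt(rest, -60)
  rest_graded <- resting_potential(p, na_present = FALSE)
  expect_gt(rest_graded, p$e_k)
  expect_lt(rest_graded, p$e_leak)
})

test_that("model variants map onto the four studied configurations", {
  expect_equal(model_variant("spiking")$na_mode, "stochastic")
  expect_equal(model_variant("det_na")$na_mode, "deterministic")
  expect_equal(model_variant("det_k")$k_mode, "deterministic")
  g <- model_variant("graded")
  expect_equal(g$na_mode, "absent")
  expect_equal(g$k_mode, "stochastic")
})
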