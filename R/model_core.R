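#' Biophysical parameters of the single-compartment model
#'
#' Returns the full parameter set of the squid-axon Hodgkin-Huxley single
#' compartment used throughout the package, in the modern voltage
#' convention. Units: capacitance uF/cm^2, conductances mS/cm^2, reversal
#' potentials mV, area um^2; channel counts are integers over the whole
#' compartment.
#'
#' The defaults correspond to a 100 um^2 patch with the canonical squid
#' channel densities (60 Na+ and 18 K+ channels per um^2, i.e. 20 pS
#' single-channel conductance matched to the maximal conductances).
#'
#' @param membrane_capacitance specific capacitance (uF/cm^2)
#' @param g_na_max,g_k_max,g_leak maximal specific conductances (mS/cm^2)
#' @param e_na,e_k,e_leak reversal potentials (mV)
#' @param area membrane area (um^2)
#' @param n_na,n_k integer channel counts for the stochastic populations
#' @return an object of class `biophys_params` (a named list)
#' @export
biophys_params <- function(membrane_capacitance = 1,
                           g_na_max = 120, g_k_max = 36, g_leak = 0.3,
                           e_na = 50, e_k = -77, e_leak = -54.4,
                           area = 100, n_na = 6000L, n_k = 1800L) {
  stopifnot(
    membrane_capacitance > 0,
    g_na_max >= 0, g_k_max >= 0, g_leak >= 0,
    e_k < e_leak, e_leak < e_na,
    area > 0, n_na > 0, n_k > 0
  )
  structure(
    list(
      membrane_capacitance = membrane_capacitance,
      g_na_max = g_na_max, g_k_max = g_k_max, g_leak = g_leak,
      e_na = e_na, e_k = e_k, e_leak = e_leak,
      area = area, n_na = as.integer(n_na), n_k = as.integer(n_k)
    ),
    class = "biophys_params"
  )
}

#' @export
print.biophys_params <- function(x, ...) {
  cat("<biophys_params>\n")
  cat(sprintf("  Cm = %g uF/cm^2, area = %g um^2\n",
              x$membrane_capacitance, x$area))
  cat(sprintf("  gNa = %g, gK = %g, gL = %g mS/cm^2\n",
              x$g_na_max, x$g_k_max, x$g_leak))
  cat(sprintf("  ENa = %g, EK = %g, EL = %g mV\n", x$e_na, x$e_k, x$e_leak))
  cat(sprintf("  N_Na = %d, N_K = %d channels\n", x$n_na, x$n_k))
  invisible(x)
}

# x / (1 - exp(-x/y)) with the removable singularity at x = 0 evaluated
# by its series limit y + x/2.
vtrap <- function(x, y) {
  small <- abs(x / y) < 1e-7
  out <- x
  out[small] <- y + x[small] / 2
  out[!small] <- x[!small] / (1 - exp(-x[!small] / y))
  out
}

#' Voltage-dependent gating rates
#'
#' Evaluates the six first-order Hodgkin-Huxley transition rates (ms^-1)
#' at membrane potential `v` (mV). Removable singularities (alpha_m at
#' -40 mV, alpha_n at -55 mV) are evaluated by their analytic limits.
#'
#' @param v membrane potential, mV (vectorised)
#' @return a `gating_rates` list with elements `alpha_m`, `beta_m`,
#'   `alpha_h`, `beta_h`, `alpha_n`, `beta_n`, each the same length as `v`
#' @examples
#' gating_rates(-40)$alpha_m  # exactly 1 (limit value)
#' @export
gating_rates <- function(v) {
  if (!all(is.finite(v))) {
    stop("`v` must be finite", call. = FALSE)
  }
  structure(
    list(
      alpha_m = 0.1 * vtrap(v + 40, 10),
      beta_m  = 4 * exp(-(v + 65) / 18),
      alpha_h = 0.07 * exp(-(v + 65) / 20),
      beta_h  = 1 / (1 + exp(-(v + 35) / 10)),
      alpha_n = 0.01 * vtrap(v + 55, 10),
      beta_n  = 0.125 * exp(-(v + 65) / 80)
    ),
    class = "gating_rates"
  )
}

#' Steady-state activation and time constants
#'
#' `x_inf = alpha/(alpha+beta)` and `tau = 1/(alpha+beta)` (ms) for each
#' of the three gates.
#'
#' @inheritParams gating_rates
#' @return tibble with columns `v`, `m_inf`, `h_inf`, `n_inf`, `tau_m`,
#'   `tau_h`, `tau_n`
#' @export
gating_steady_state <- function(v) {
  r <- gating_rates(v)
  tibble::tibble(
    v = v,
    m_inf = r$alpha_m / (r$alpha_m + r$beta_m),
    h_inf = r$alpha_h / (r$alpha_h + r$beta_h),
    n_inf = r$alpha_n / (r$alpha_n + r$beta_n),
    tau_m = 1 / (r$alpha_m + r$beta_m),
    tau_h = 1 / (r$alpha_h + r$beta_h),
    tau_n = 1 / (r$alpha_n + r$beta_n)
  )
}

#' Markov gating scheme for a channel population
#'
#' Builds the full state-transition scheme of one channel type. The Na+
#' channel is the 8-state m0..m3 x h0/h1 lattice (20 transitions, one
#' conducting state m3h1); the K+ channel is the 5-state n0..n4 chain
#' (8 transitions, conducting state n4). Together the two schemes have
#' 13 states and 28 transitions.
#'
#' @param kind `"Na"` or `"K"`
#' @return a `channel_scheme` list: `kind`, `states` (character),
#'   `conducting_state`, and `transitions`, a tibble with columns `from`,
#'   `to`, `gate` (which gate flips), `mult` (multiplicity), `dir`
#'   (`"alpha"` or `"beta"`)
#' @export
channel_scheme <- function(kind = c("Na", "K")) {
  kind <- match.arg(kind)
  if (kind == "Na") {
    states <- as.vector(outer(0:3, 0:1, function(i, j) {
      sprintf("m%dh%d", i, j)
    }))
    tr <- list()
    for (j in 0:1) {
      for (i in 0:2) {
        tr[[length(tr) + 1]] <- list(
          from = sprintf("m%dh%d", i, j), to = sprintf("m%dh%d", i + 1, j),
          gate = "m", mult = 3 - i, dir = "alpha"
        )
      }
      for (i in 1:3) {
        tr[[length(tr) + 1]] <- list(
          from = sprintf("m%dh%d", i, j), to = sprintf("m%dh%d", i - 1, j),
          gate = "m", mult = i, dir = "beta"
        )
      }
    }
    for (i in 0:3) {
      tr[[length(tr) + 1]] <- list(
        from = sprintf("m%dh0", i), to = sprintf("m%dh1", i),
        gate = "h", mult = 1, dir = "alpha"
      )
      tr[[length(tr) + 1]] <- list(
        from = sprintf("m%dh1", i), to = sprintf("m%dh0", i),
        gate = "h", mult = 1, dir = "beta"
      )
    }
    conducting <- "m3h1"
  } else {
    states <- sprintf("n%d", 0:4)
    tr <- list()
    for (i in 0:3) {
      tr[[length(tr) + 1]] <- list(
        from = sprintf("n%d", i), to = sprintf("n%d", i + 1),
        gate = "n", mult = 4 - i, dir = "alpha"
      )
    }
    for (i in 1:4) {
      tr[[length(tr) + 1]] <- list(
        from = sprintf("n%d", i), to = sprintf("n%d", i - 1),
        gate = "n", mult = i, dir = "beta"
      )
    }
    conducting <- "n4"
  }
  transitions <- dplyr::bind_rows(lapply(tr, tibble::as_tibble))
  structure(
    list(kind = kind, states = states, conducting_state = conducting,
         transitions = transitions),
    class = "channel_scheme"
  )
}

#' @export
print.channel_scheme <- function(x, ...) {
  cat(sprintf("<channel_scheme: %s> %d states, %d transitions (conducting: %s)\n",
              x$kind, length(x$states), nrow(x$transitions),
              x$conducting_state))
  invisible(x)
}

#' Transition-rate matrix of a scheme at fixed voltage
#'
#' Evaluates the infinitesimal generator Q of the scheme's Markov chain at
#' membrane potential `v`: `Q[i, j]` is the per-channel rate (ms^-1) from
#' state i to state j, with diagonal `-rowSums`.
#'
#' @param scheme a [channel_scheme()]
#' @param v membrane potential (mV, scalar)
#' @return square numeric matrix with dimnames = states
#' @export
rate_matrix <- function(scheme, v) {
  stopifnot(inherits(scheme, "channel_scheme"), length(v) == 1)
  r <- gating_rates(v)
  q <- matrix(0, length(scheme$states), length(scheme$states),
              dimnames = list(scheme$states, scheme$states))
  tr <- scheme$transitions
  rate <- numeric(nrow(tr))
  for (k in seq_len(nrow(tr))) {
    base <- r[[paste0(tr$dir[k], "_", tr$gate[k])]]
    rate[k] <- tr$mult[k] * base
    q[tr$from[k], tr$to[k]] <- q[tr$from[k], tr$to[k]] + rate[k]
  }
  diag(q) <- -rowSums(q)
  q
}

#' Equilibrium state occupancy at fixed voltage
#'
#' Solves the master equation `pi Q = 0`, `sum(pi) = 1` for the scheme's
#' stationary distribution at clamped voltage. Because the gates are
#' independent this equals the binomial product form
#' (`Binom(4, n_inf)` for K+; `Binom(3, m_inf) x Bernoulli(h_inf)` for
#' Na+), which tests exploit as a closed-form oracle.
#'
#' @inheritParams rate_matrix
#' @return named numeric vector of state probabilities
#' @export
scheme_equilibrium <- function(scheme, v) {
  q <- rate_matrix(scheme, v)
  n <- nrow(q)
  # append the normalisation constraint and solve the least-squares system
  a <- rbind(t(q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- qr.solve(a, b)
  stats::setNames(pmax(pi_hat, 0) / sum(pmax(pi_hat, 0)), rownames(q))
}

#' Resting potential of a model variant
#'
#' Root of the steady-state whole-membrane ionic current. For the graded
#' (Na+-free) variant the Na+ conductance is excluded.
#'
#' @param params a [biophys_params()]
#' @param na_present logical; include the Na+ conductance?
#' @param i_hold tonic holding current (uA/cm^2) added to the balance
#' @return resting potential, mV
#' @export
resting_potential <- function(params = biophys_params(), na_present = TRUE,
                              i_hold = 0) {
  f <- function(v) {
    ss <- gating_steady_state(v)
    i_na <- if (na_present) {
      params$g_na_max * ss$m_inf^3 * ss$h_inf * (v - params$e_na)
    } else 0
    i_k <- params$g_k_max * ss$n_inf^4 * (v - params$e_k)
    i_l <- params$g_leak * (v - params$e_leak)
    i_na + i_k + i_l - i_hold
  }
  stats::uniroot(f, c(params$e_k + 0.01, -30), tol = 1e-10)$root
}

#' Model configuration
#'
#' Declares which conductances exist and whether each voltage-gated
#' population is simulated stochastically (Gillespie) or deterministically
#' (Euler on the gating ODEs). The four variants studied are
#' (stochastic, stochastic) -- the spiking model; (deterministic,
#' stochastic); (stochastic, deterministic); and (absent, stochastic) --
#' the graded model.
#'
#' @param na_mode `"stochastic"`, `"deterministic"`, or `"absent"`
#' @param k_mode `"stochastic"` or `"deterministic"`
#' @param params a [biophys_params()]
#' @param dt integration step (s); 1e-5 s = 10 us
#' @param initial_v initial membrane potential (mV); default the variant's
#'   resting potential
#' @return a `model_config` list
#' @export
model_config <- function(na_mode = c("stochastic", "deterministic", "absent"),
                         k_mode = c("stochastic", "deterministic"),
                         params = biophys_params(),
                         dt = 1e-5,
                         initial_v = NULL) {
  na_mode <- match.arg(na_mode)
  k_mode <- match.arg(k_mode)
  stopifnot(dt > 0)
  if (is.null(initial_v)) {
    initial_v <- resting_potential(params, na_present = na_mode != "absent")
  }
  structure(
    list(na_mode = na_mode, k_mode = k_mode, params = params,
         dt = dt, initial_v = initial_v),
    class = "model_config"
  )
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> Na: %s, K: %s, dt = %g s, V0 = %.2f mV\n",
              x$na_mode, x$k_mode, x$dt, x$initial_v))
  invisible(x)
}

#' The four canonical model variants
#'
#' Convenience constructor for the canonical variants by name.
#'
#' @param variant one of `"spiking"` (stochastic Na+/stochastic K+),
#'   `"det_na"` (deterministic Na+/stochastic K+), `"det_k"` (stochastic
#'   Na+/deterministic K+), `"graded"` (no Na+, stochastic K+)
#' @param ... passed to [model_config()]
#' @export
model_variant <- function(variant = c("spiking", "det_na", "det_k", "graded"),
                          ...) {
  variant <- match.arg(variant)
  modes <- switch(variant,
    spiking = c("stochastic", "stochastic"),
    det_na  = c("deterministic", "stochastic"),
    det_k   = c("stochastic", "deterministic"),
    graded  = c("absent", "stochastic")
  )
  model_config(na_mode = modes[1], k_mode = modes[2], ...)
}
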