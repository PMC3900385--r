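#' Draw channel-state occupancies from the clamped-voltage equilibrium
#'
#' Samples integer occupancies for a stochastic population from the
#' stationary distribution of its gating scheme at voltage `v` (a
#' multinomial draw over the binomial-product equilibrium).
#'
#' @param scheme a [channel_scheme()]
#' @param n_channels population size
#' @param v membrane potential (mV)
#' @return named integer vector of occupancies summing to `n_channels`
#' @export
equilibrium_counts <- function(scheme, n_channels, v) {
  p <- scheme_equilibrium(scheme, v)
  stats::setNames(as.integer(stats::rmultinom(1, n_channels, p)), names(p))
}

#' One Gillespie window for a channel scheme
#'
#' Advances integer state occupancies through `n_windows` consecutive
#' windows of length `window` ms with per-channel transition rates frozen
#' at voltage `v`. Exact event-driven simulation: exponential waiting
#' times at total propensity lambda, transitions selected with probability
#' proportional to rate x source occupancy; waiting time left over at a
#' window boundary is discarded.
#'
#' @param counts named integer occupancies (in `scheme$states` order)
#' @param scheme a [channel_scheme()]
#' @param v membrane potential (mV)
#' @param window window length (ms)
#' @param n_windows number of consecutive windows
#' @return integer matrix, `n_windows` rows x states columns: occupancy at
#'   the end of each window
#' @export
gillespie_update <- function(counts, scheme, v, window, n_windows = 1) {
  stopifnot(length(counts) == length(scheme$states), all(counts >= 0))
  r <- gating_rates(v)
  tr <- scheme$transitions
  rates <- vapply(seq_len(nrow(tr)), function(k) {
    tr$mult[k] * r[[paste0(tr$dir[k], "_", tr$gate[k])]]
  }, numeric(1))
  out <- gillespie_generic(
    as.integer(counts),
    match(tr$from, scheme$states) - 1L,
    match(tr$to, scheme$states) - 1L,
    rates, window, as.integer(n_windows)
  )
  colnames(out) <- scheme$states
  out
}

#' Simulate the single-compartment model
#'
#' Integrates the membrane current-balance equation with forward Euler at
#' the configured step (default 10 us) while advancing each voltage-gated
#' population either deterministically (Euler on the gating ODEs) or
#' stochastically (exact Gillespie within each step, rates frozen at the
#' step's voltage). Initial occupancies/gates are drawn from the
#' equilibrium at `initial_v`; an optional burn-in at the stimulus mean is
#' prepended and discarded.
#'
#' @param model a [model_config()] or [model_variant()]
#' @param stimulus a [current_trace()] whose `dt` matches the model's
#' @param seed RNG seed (initial state draw + Gillespie)
#' @param burn_in burn-in duration to prepend and discard (s)
#' @param record_extra also record open fractions and the Na+ current
#' @return a `simulation_result` list: `v` (mV), `i_k` (total K+ current
#'   incl. the K+ leak branch, uA/cm^2, outward positive), `dt` (s),
#'   `spike_times` left unset, plus `open_na`, `open_k`, `i_na` when
#'   requested, and provenance (`model`, `seed`)
#' @export
simulate_trial <- function(model, stimulus, seed = 1L, burn_in = 0.1,
                           record_extra = FALSE) {
  stopifnot(inherits(model, "model_config"),
            inherits(stimulus, "current_trace"))
  if (abs(stimulus$dt - model$dt) > 1e-12) {
    stop("stimulus dt does not match model dt", call. = FALSE)
  }
  p <- model$params
  leak <- split_leak(p$g_leak, p$e_leak, p$e_k, p$e_na)
  n_burn <- round(burn_in / model$dt)
  stim <- c(rep(mean(stimulus$values), n_burn), stimulus$values)

  na_mode <- match(model$na_mode, c("stochastic", "deterministic", "absent")) - 1L
  k_mode <- match(model$k_mode, c("stochastic", "deterministic")) - 1L

  res <- with_seed(seed, {
    na0 <- if (na_mode == 0L) {
      equilibrium_counts(channel_scheme("Na"), p$n_na, model$initial_v)
    } else integer(8)
    k0 <- if (k_mode == 0L) {
      equilibrium_counts(channel_scheme("K"), p$n_k, model$initial_v)
    } else integer(5)
    ss <- gating_steady_state(model$initial_v)
    sim_core(stim, model$dt * 1000, unclass(p), na_mode, k_mode,
             model$initial_v, na0, k0, ss$m_inf, ss$h_inf, ss$n_inf,
             leak$g_leak_k, record_extra)
  })

  keep <- (n_burn + 1):length(stim)
  out <- list(
    v = res$v[keep], i_k = res$i_k[keep], dt = model$dt,
    model = model, seed = seed, burn_in = burn_in
  )
  if (record_extra) {
    out$open_na <- res$open_na[keep]
    out$open_k <- res$open_k[keep]
    out$i_na <- res$i_na[keep]
  }
  structure(out, class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "<simulation_result> %d samples @ dt = %g s; V in [%.1f, %.1f] mV (Na: %s, K: %s)\n",
    length(x$v), x$dt, min(x$v), max(x$v),
    x$model$na_mode, x$model$k_mode))
  invisible(x)
}

#' Simulate a set of trials
#'
#' Runs [simulate_trial()] once per stimulus trace with deterministic
#' per-trial child seeds. Channel noise is independent across trials even
#' when the stimulus is frozen.
#'
#' @param model a [model_config()]
#' @param stimuli list of [current_trace()] (one per trial)
#' @param seed master seed
#' @param ... passed to [simulate_trial()]
#' @return list of `simulation_result`
#' @export
simulate_trials <- function(model, stimuli, seed = 1L, ...) {
  seeds <- child_seeds(seed, length(stimuli))
  purrr::map2(stimuli, seeds, function(st, s) {
    simulate_trial(model, st, seed = s, ...)
  })
}

#' Detect spikes by threshold crossing
#'
#' A spike is an upward crossing of `threshold` separated from the
#' previous spike by at least `dead_time`.
#'
#' @param v voltage samples (mV) or a `simulation_result`
#' @param dt sample interval (s); taken from the result if one is given
#' @param threshold detection threshold (mV)
#' @param dead_time minimum spike separation (ms)
#' @return numeric vector of spike times (s), possibly empty
#' @export
detect_spikes <- function(v, dt = NULL, threshold = -20, dead_time = 2) {
  if (inherits(v, "simulation_result")) {
    dt <- v$dt
    v <- v$v
  }
  stopifnot(!is.null(dt))
  up <- which(v[-1] > threshold & v[-length(v)] <= threshold)
  if (length(up) == 0) return(numeric(0))
  times <- up * dt
  keep <- c(TRUE, diff(times) >= dead_time / 1000)
  # enforce the dead time sequentially (diff alone can chain-violate)
  out <- times[1]
  for (t in times[-1]) {
    if (t - out[length(out)] >= dead_time / 1000) out <- c(out, t)
  }
  out
}

#' Find the tonic current holding the mean membrane potential at a target
#'
#' Bisection on the holding current: each candidate is evaluated by
#' simulating the model for `duration` seconds (after burn-in) under a
#' constant current and measuring the mean voltage. Fails if the target
#' provokes sustained spiking in Na+-bearing models.
#'
#' @param model a [model_config()]
#' @param target_mean_v target mean membrane potential (mV)
#' @param tolerance acceptable deviation (mV)
#' @param duration evaluation window per candidate (s)
#' @param seed RNG seed
#' @param max_iter bisection iterations
#' @return list: `current` (uA/cm^2), `achieved_mean_v` (mV)
#' @export
find_holding_current <- function(model, target_mean_v, tolerance = 0.5,
                                 duration = 2, seed = 1L, max_iter = 30) {
  p <- model$params
  ss <- gating_steady_state(target_mean_v)
  i_na <- if (model$na_mode != "absent") {
    p$g_na_max * ss$m_inf^3 * ss$h_inf * (target_mean_v - p$e_na)
  } else 0
  i0 <- i_na + p$g_k_max * ss$n_inf^4 * (target_mean_v - p$e_k) +
    p$g_leak * (target_mean_v - p$e_leak)

  mean_v_at <- function(i_hold) {
    stim <- current_trace(rep(i_hold, round(duration / model$dt)), model$dt)
    sim <- simulate_trial(model, stim, seed = seed, burn_in = 0.2)
    sp <- detect_spikes(sim)
    if (model$na_mode != "absent" && length(sp) > duration) {
      stop(sprintf(
        "holding at %.1f mV causes sustained spiking (%d spikes in %g s)",
        target_mean_v, length(sp), duration), call. = FALSE)
    }
    mean(sim$v)
  }

  lo <- i0 - 1
  hi <- i0 + 1
  v_lo <- mean_v_at(lo)
  v_hi <- mean_v_at(hi)
  while (v_lo > target_mean_v && lo > i0 - 10) {
    lo <- lo - 1
    v_lo <- mean_v_at(lo)
  }
  while (v_hi < target_mean_v && hi < i0 + 10) {
    hi <- hi + 1
    v_hi <- mean_v_at(hi)
  }
  cur <- i0
  v_cur <- mean_v_at(cur)
  iter <- 0
  while (abs(v_cur - target_mean_v) > tolerance && iter < max_iter) {
    if (v_cur > target_mean_v) hi <- cur else lo <- cur
    cur <- (lo + hi) / 2
    v_cur <- mean_v_at(cur)
    iter <- iter + 1
  }
  if (abs(v_cur - target_mean_v) > tolerance) {
    stop(sprintf("holding-current search did not converge (reached %.2f mV)",
                 v_cur), call. = FALSE)
  }
  list(current = cur, achieved_mean_v = v_cur)
}

#' Standard deviation of the spontaneous voltage noise at a holding level
#'
#' Simulates the model under a constant holding current and returns the SD
#' of the membrane potential after burn-in; fails if spikes occur.
#'
#' @param model a [model_config()]
#' @param holding_current tonic current (uA/cm^2)
#' @param duration measurement window (s)
#' @param seed RNG seed
#' @return list: `sd` (mV), `mean_v` (mV)
#' @export
voltage_noise_sd <- function(model, holding_current = 0, duration = 1,
                             seed = 1L) {
  stim <- current_trace(rep(holding_current, round(duration / model$dt)),
                        model$dt)
  sim <- simulate_trial(model, stim, seed = seed, burn_in = 0.2)
  if (model$na_mode != "absent" && length(detect_spikes(sim)) > 0) {
    stop("spiking detected during voltage-noise measurement", call. = FALSE)
  }
  list(sd = stats::sd(sim$v), mean_v = mean(sim$v))
}
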