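# Physical constants
.avogadro <- 6.02214076e23        # mol^-1
.faraday <- 96485.33212           # C/mol
.elementary_charge <- .faraday / .avogadro  # C

#' Split the leak conductance into K+- and Na+-permeable branches
#'
#' Unique pair `(g_leak_k, g_leak_na)` with `g_leak_k + g_leak_na =
#' g_leak` and `g_leak_k E_K + g_leak_na E_Na = g_leak E_leak`, so the
#' two-branch leak reproduces the original leak current at every voltage.
#' The K+ branch enters the pump-load accounting.
#'
#' @param g_leak leak conductance (mS/cm^2)
#' @param e_leak,e_k,e_na reversal potentials (mV); requires
#'   `e_k < e_leak < e_na`
#' @return list with `g_leak_k` and `g_leak_na` (mS/cm^2)
#' @export
split_leak <- function(g_leak, e_leak, e_k, e_na) {
  if (e_leak < e_k || e_leak > e_na) {
    stop("`e_leak` must lie within (e_k, e_na)", call. = FALSE)
  }
  g_k <- g_leak * (e_na - e_leak) / (e_na - e_k)
  list(g_leak_k = g_k, g_leak_na = g_leak - g_k)
}

#' ATP consumption from the total K+ current
#'
#' Converts the integrated K+ charge into the Na+/K+-ATPase load: the
#' pump imports 2 K+ per ATP, so ATP/s = Q_K / (2 e) / duration, with
#' Q_K the signed outward K+ charge over the trace (Avogadro/Faraday
#' stoichiometry N_A/(2F) per coulomb). `rectify = TRUE` counts only
#' outward-flowing charge instead of the signed integral.
#'
#' @param i_k total K+ current samples (uA/cm^2, outward positive):
#'   delayed rectifier plus the K+-permeable leak branch
#' @param dt sample interval (s)
#' @param area membrane area (um^2)
#' @param rectify count only outward (positive) current
#' @return ATP molecules per second
#' @export
atp_consumption <- function(i_k, dt, area = 100, rectify = FALSE) {
  stopifnot(dt > 0, area > 0)
  if (rectify) i_k <- pmax(i_k, 0)
  duration <- length(i_k) * dt
  q <- sum(i_k) * dt * 1e-6 * (area * 1e-8)  # uA/cm^2 -> A/cm^2, um^2 -> cm^2
  q / (2 * .elementary_charge) / duration
}

#' Energy efficiency of information coding
#'
#' @param info_rate information rate (bits/s)
#' @param atp_rate ATP consumption (molecules/s); must be positive
#' @return efficiency, bits per ATP molecule
#' @export
energy_efficiency <- function(info_rate, atp_rate) {
  if (any(atp_rate <= 0)) stop("`atp_rate` must be positive", call. = FALSE)
  info_rate / atp_rate
}

#' Total K+ current implied by a pseudo-generator voltage trace
#'
#' Recomputes the delayed-rectifier K+ current along an interpolated
#' (spike-excised) voltage trace by integrating the deterministic n-gate
#' ODE driven by that voltage, and adds the K+-permeable leak branch.
#' Used to account for the energy of pseudo-generator potentials.
#'
#' @param v voltage samples (mV)
#' @param dt sample interval (s)
#' @param params a [biophys_params()]
#' @return total K+ current trace (uA/cm^2, outward positive)
#' @export
pseudo_generator_ik <- function(v, dt, params = biophys_params()) {
  leak <- split_leak(params$g_leak, params$e_leak, params$e_k, params$e_na)
  dt_ms <- dt * 1000
  n <- numeric(length(v))
  ss <- gating_steady_state(v[1])
  n[1] <- ss$n_inf
  r <- gating_rates(v)
  for (i in seq_along(v)[-1]) {
    n[i] <- n[i - 1] + dt_ms *
      (r$alpha_n[i - 1] * (1 - n[i - 1]) - r$beta_n[i - 1] * n[i - 1])
  }
  (params$g_k_max * n^4 + leak$g_leak_k) * (v - params$e_k)
}

#' Energy report for a set of trials
#'
#' Summarises ATP consumption across trials and attaches an information
#' rate to form the bits-per-ATP efficiency.
#'
#' @param i_k_trials list of K+ current traces or samples x trials matrix
#' @param dt sample interval (s)
#' @param area membrane area (um^2)
#' @param info_rate information rate to attach (bits/s), optional
#' @param rectify passed to [atp_consumption()]
#' @return an `energy_report`: `atp_per_second` (trial mean),
#'   `atp_by_trial`, `info_rate`, `efficiency` (bits/ATP)
#' @export
energy_report <- function(i_k_trials, dt, area = 100, info_rate = NA_real_,
                          rectify = FALSE) {
  m <- as_trial_matrix(i_k_trials)
  atp <- apply(m, 2, atp_consumption, dt = dt, area = area,
               rectify = rectify)
  structure(
    list(atp_per_second = mean(atp), atp_by_trial = atp,
         info_rate = info_rate,
         efficiency = if (is.finite(info_rate) && mean(atp) > 0) {
           info_rate / mean(atp)
         } else NA_real_),
    class = "energy_report"
  )
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("<energy_report> %.3g ATP/s", x$atp_per_second))
  if (is.finite(x$info_rate)) {
    cat(sprintf("; %.1f bits/s -> %.3g bits/ATP", x$info_rate,
                x$efficiency))
  }
  cat("\n")
  invisible(x)
}
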