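#' Reproduce the pipeline's headline quantities
#'
#' Runs the full pipeline end-to-end at a configurable trial budget and
#' returns the headline quantities of the analysis: maximum spike-train
#' information (direct method) and its firing-rate companion, maximum
#' graded and pseudo-generator information (Gaussian-channel bound),
#' the action-potential footprint experiment (baseline, random insertion,
#' response-only and matched-stimulus coherence), and the sub-threshold
#' information rates at -77 and -70 mV holding potentials.
#'
#' The default budget is the "desk" preset: 20 one-second trials per
#' session. All randomness derives from `seed`.
#'
#' @param seed master seed
#' @param n_trials trials per session
#' @param duration trial length (s)
#' @param verbose print progress messages
#' @return tibble with columns `quantity`, `value`, `units`, `n_trials`
#' @export
reproduce_headline_results <- function(seed = 1L, n_trials = 20,
                                       duration = 1, verbose = FALSE) {
  seed <- as.integer(seed) %% 100000L
  say <- function(...) if (verbose) message(sprintf(...))
  dt <- 1e-5
  out <- list()
  add <- function(quantity, value, units, n = n_trials) {
    out[[length(out) + 1]] <<- tibble::tibble(
      quantity = quantity, value = value, units = units, n_trials = n)
  }

  # -- spiking model, low-mean/high-SD corner: direct-method information
  say("spiking model at the low-mean/high-SD corner ...")
  run_spk <- run_condition("spiking", 1, 10, n_frozen = n_trials,
                           n_unfrozen = n_trials, duration = duration,
                           seed = seed + 11L)
  est <- direct_method_info(condition_spike_trains(run_spk, "frozen"),
                            condition_spike_trains(run_spk, "unfrozen"),
                            duration)
  add("spike_info_max", est$info_rate, "bits/s")

  # pseudo-generator potential from the same frozen voltage traces
  pg <- vapply(run_spk$frozen, function(s) pseudo_generator(s),
               numeric(length(run_spk$frozen[[1]]$v)))
  add("pseudo_generator_info_max", analog_info(pg, dt)$info, "bits/s")

  # -- graded model, same corner: Gaussian-channel information
  say("graded model at the low-mean/high-SD corner ...")
  run_grd <- run_condition("graded", 1, 10, n_frozen = n_trials,
                           n_unfrozen = 0, duration = duration,
                           seed = seed + 12L)
  add("graded_info_max",
      analog_info(condition_voltages(run_grd, "frozen"), dt)$info,
      "bits/s")

  # -- firing rate at the high-mean/high-SD corner
  say("firing rate at the high-mean/high-SD corner ...")
  n_rate <- max(10L, ceiling(n_trials / 2))
  run_hi <- run_condition("spiking", 10, 10, n_frozen = 0,
                          n_unfrozen = n_rate, duration = duration,
                          seed = seed + 13L)
  rate <- mean(vapply(run_hi$unfrozen, function(s) {
    length(detect_spikes(s)) / duration
  }, numeric(1)))
  add("firing_rate_high", rate, "spikes/s", n_rate)

  # -- footprint experiment on the graded model (intermediate stimulus)
  say("footprint experiment on the graded model ...")
  run_fp <- run_condition("graded", 5, 5, n_frozen = n_trials,
                          n_unfrozen = n_trials, duration = duration,
                          seed = seed + 14L)
  vm <- condition_voltages(run_fp, "frozen")
  add("footprint_baseline_info", analog_info(vm, dt)$info, "bits/s")

  fp80 <- insert_footprints(vm, footprint_plan("random", 80,
                                               seed = seed + 15L), dt)
  add("footprint_random80_info", analog_info(fp80$traces, dt)$info,
      "bits/s")

  sm <- as_trial_matrix(run_fp$unfrozen_stimuli)
  rm_ <- condition_voltages(run_fp, "unfrozen")
  coh_base <- wiener_pipeline(sm, rm_, dt)$coherence_info
  fr <- insert_footprints(rm_, footprint_plan("random", 80,
                                              seed = seed + 16L), dt)
  coh_resp <- wiener_pipeline(sm, fr$traces, dt)$coherence_info
  add("footprint_coherence80_info", coh_resp, "bits/s")
  sm80 <- interpolate_stimulus(sm, fr$positions, 6, dt)
  coh_matched <- wiener_pipeline(sm80, fr$traces, dt)$coherence_info
  add("footprint_coherence_baseline", coh_base, "bits/s")
  add("footprint_coherence80_matched", coh_matched, "bits/s")
  add("footprint_loss_pct", 100 * (coh_base - coh_matched) / coh_base, "%")

  # -- sub-threshold information at held potentials
  say("sub-threshold runs at -77 and -70 mV ...")
  run_77 <- run_condition("det_na", 0, 1, n_frozen = n_trials,
                          n_unfrozen = 0, duration = duration,
                          seed = seed + 17L, holding_v = -77)
  add("subthreshold_info_m77",
      analog_info(condition_voltages(run_77, "frozen"), dt)$info,
      "bits/s")
  run_70 <- run_condition("spiking", 0, 1, n_frozen = n_trials,
                          n_unfrozen = 0, duration = duration,
                          seed = seed + 18L, holding_v = -70)
  add("subthreshold_info_m70",
      analog_info(condition_voltages(run_70, "frozen"), dt)$info,
      "bits/s")

  dplyr::bind_rows(out)
}
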