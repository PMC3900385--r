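#' Simulate one stimulus condition (frozen and/or unfrozen sessions)
#'
#' Generates band-limited noise stimuli, optionally finds a tonic holding
#' current for a target mean potential, and simulates the requested model
#' variant over both session types. This is the workhorse behind the
#' experiment grids: every downstream estimator consumes its output.
#'
#' @param variant model variant name (see [model_variant()])
#' @param stim_mean,stim_sd stimulus mean and SD (uA/cm^2)
#' @param n_frozen,n_unfrozen trials per session (0 skips a session)
#' @param duration trial length (s)
#' @param seed master seed
#' @param snr extrinsic signal-to-noise ratio Omega (NULL = none)
#' @param holding_v target mean membrane potential (mV); a tonic current
#'   is found by bisection and added to the stimulus
#' @param dt integration step (s)
#' @param cutoff stimulus cutoff (Hz)
#' @return a `condition_run` list: `frozen` / `unfrozen` (lists of
#'   `simulation_result`), matching stimulus lists, `model`, `holding`
#' @export
run_condition <- function(variant, stim_mean, stim_sd,
                          n_frozen = 20, n_unfrozen = 20, duration = 1,
                          seed = 1L, snr = NULL, holding_v = NULL,
                          dt = 1e-5, cutoff = 300) {
  model <- model_variant(variant, dt = dt)
  holding <- NULL
  offset <- 0
  if (!is.null(holding_v)) {
    model$initial_v <- holding_v
    holding <- find_holding_current(model, holding_v, seed = seed)
    offset <- holding$current
  }

  session <- function(frozen, n_trials, session_seed) {
    if (n_trials == 0) return(list(stimuli = NULL, sims = NULL))
    cfg <- stimulus_config(mean = stim_mean, sd = stim_sd, cutoff = cutoff,
                           duration = duration, dt = dt,
                           n_trials = n_trials, frozen = frozen,
                           snr = snr, seed = session_seed)
    stimuli <- band_limited_noise(cfg)
    if (offset != 0) {
      stimuli <- lapply(stimuli, function(tr) {
        current_trace(tr$values + offset, tr$dt, tr$meta)
      })
    }
    sims <- simulate_trials(model, stimuli, seed = session_seed + 1L)
    list(stimuli = stimuli, sims = sims)
  }

  fro <- session(TRUE, n_frozen, seed)
  unf <- session(FALSE, n_unfrozen, seed + 1000L)
  structure(
    list(variant = variant, stim_mean = stim_mean, stim_sd = stim_sd,
         duration = duration, dt = dt, seed = seed, snr = snr,
         holding = holding,
         frozen = fro$sims, frozen_stimuli = fro$stimuli,
         unfrozen = unf$sims, unfrozen_stimuli = unf$stimuli,
         model = model),
    class = "condition_run"
  )
}

#' @export
print.condition_run <- function(x, ...) {
  cat(sprintf(
    "<condition_run> %s, mean %g / sd %g uA/cm^2, %d frozen + %d unfrozen x %g s\n",
    x$variant, x$stim_mean, x$stim_sd,
    length(x$frozen), length(x$unfrozen), x$duration))
  invisible(x)
}

condition_spike_trains <- function(run, session = c("frozen", "unfrozen")) {
  session <- match.arg(session)
  lapply(run[[session]], detect_spikes)
}

condition_voltages <- function(run, session = c("frozen", "unfrozen")) {
  as_trial_matrix(run[[match.arg(session)]])
}

condition_ik <- function(run, session = c("frozen", "unfrozen")) {
  do.call(cbind, lapply(run[[match.arg(session)]], function(s) s$i_k))
}

#' Summarise a simulated condition
#'
#' Computes the full metric set for one condition: firing rate,
#' direct-method entropies (spiking variants with both sessions),
#' Gaussian-channel information of the voltage (analogue variants) and of
#' the pseudo-generator potential (spiking variants), ATP consumption and
#' bits-per-ATP efficiency.
#'
#' @param run a [run_condition()] result
#' @param band analysis band (Hz)
#' @return one-row tibble
#' @export
condition_summary <- function(run, band = c(0, 300)) {
  spiking <- run$variant != "graded"
  dt <- run$dt

  rate <- NA_real_
  sims_for_rate <- if (!is.null(run$unfrozen)) run$unfrozen else run$frozen
  if (spiking && !is.null(sims_for_rate)) {
    rate <- mean(vapply(sims_for_rate, function(s) {
      length(detect_spikes(s)) / run$duration
    }, numeric(1)))
  }

  total <- noise <- spike_info <- NA_real_
  if (spiking && !is.null(run$frozen) && !is.null(run$unfrozen)) {
    est <- direct_method_info(condition_spike_trains(run, "frozen"),
                              condition_spike_trains(run, "unfrozen"),
                              run$duration)
    total <- est$total_entropy_rate
    noise <- est$noise_entropy_rate
    spike_info <- est$info_rate
  }

  graded_info <- pseudo_info <- NA_real_
  pseudo_atp <- NA_real_
  if (!is.null(run$frozen)) {
    if (!spiking) {
      graded_info <- analog_info(condition_voltages(run, "frozen"), dt,
                                 band)$info
    } else {
      pg <- vapply(run$frozen, function(s) pseudo_generator(s),
                   numeric(length(run$frozen[[1]]$v)))
      pseudo_info <- analog_info(pg, dt, band)$info
      pseudo_atp <- mean(apply(pg, 2, function(v) {
        atp_consumption(pseudo_generator_ik(v, dt, run$model$params), dt,
                        run$model$params$area)
      }))
    }
  }

  sims_for_energy <- if (!is.null(run$unfrozen)) run$unfrozen else run$frozen
  atp <- mean(apply(do.call(cbind, lapply(sims_for_energy, `[[`, "i_k")),
                    2, atp_consumption, dt = dt,
                    area = run$model$params$area))

  info <- if (spiking) spike_info else graded_info
  tibble::tibble(
    variant = run$variant, stim_mean = run$stim_mean,
    stim_sd = run$stim_sd, snr = if (is.null(run$snr)) Inf else run$snr,
    firing_rate = rate,
    total_entropy = total, noise_entropy = noise,
    info_rate = info,
    bits_per_spike = if (spiking && is.finite(rate) && rate > 0) {
      spike_info / rate
    } else NA_real_,
    pseudo_info = pseudo_info,
    atp_per_s = atp, pseudo_atp_per_s = pseudo_atp,
    efficiency = if (is.finite(info) && atp > 0) info / atp else NA_real_,
    pseudo_efficiency = if (is.finite(pseudo_info) && is.finite(pseudo_atp) &&
                            pseudo_atp > 0) {
      pseudo_info / pseudo_atp
    } else NA_real_
  )
}

#' Experiment specification
#'
#' Declares a reproducible experiment: a stimulus grid, the model
#' variants, the trial budget and the master seed. The `"desk"` preset
#' (20 x 1 s trials) trades estimator variance for runtime against the
#' full 60-trial protocol.
#'
#' @param kind experiment family
#' @param means,sds stimulus grid (uA/cm^2)
#' @param variants model variants to run
#' @param n_frozen,n_unfrozen trials per session
#' @param duration trial length (s)
#' @param seed master seed
#' @param snr extrinsic SNR (NULL = none)
#' @param preset `"desk"` (20 trials) or `"paper"` (60 trials); overrides
#'   the trial counts when given
#' @return an `experiment_spec` list
#' @export
experiment_spec <- function(kind = c("grid", "channel_swap", "subthreshold",
                                     "footprint", "extrinsic_noise",
                                     "energy"),
                            means = c(1, 10), sds = c(1, 10),
                            variants = "spiking",
                            n_frozen = 20, n_unfrozen = 20, duration = 1,
                            seed = 1L, snr = NULL, preset = NULL) {
  kind <- match.arg(kind)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "paper"))
    n_frozen <- n_unfrozen <- if (preset == "desk") 20L else 60L
  }
  structure(
    list(kind = kind, means = means, sds = sds, variants = variants,
         n_frozen = n_frozen, n_unfrozen = n_unfrozen,
         duration = duration, seed = as.integer(seed), snr = snr),
    class = "experiment_spec"
  )
}

#' Run an experiment grid
#'
#' Simulates every cell of the spec's stimulus grid for every variant and
#' collects [condition_summary()] rows. Cell failures are caught, logged
#' as a warning and skipped. When `out_dir` is given the summary is
#' written as CSV together with a YAML sidecar recording the spec and
#' seed.
#'
#' @param spec an [experiment_spec()]
#' @param out_dir optional output directory
#' @return tibble of per-cell summaries
#' @export
run_experiment <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "experiment_spec"))
  cells <- tidyr::expand_grid(variant = spec$variants,
                              stim_mean = spec$means, stim_sd = spec$sds)
  res <- purrr::pmap_dfr(cells, function(variant, stim_mean, stim_sd) {
    tryCatch({
      run <- run_condition(variant, stim_mean, stim_sd,
                           n_frozen = spec$n_frozen,
                           n_unfrozen = spec$n_unfrozen,
                           duration = spec$duration,
                           seed = spec$seed, snr = spec$snr)
      condition_summary(run)
    }, error = function(e) {
      warning(sprintf("cell (%s, %g, %g) failed: %s", variant, stim_mean,
                      stim_sd, conditionMessage(e)), call. = FALSE)
      tibble::tibble(variant = variant, stim_mean = stim_mean,
                     stim_sd = stim_sd, error = conditionMessage(e))
    })
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, paste0(spec$kind, "_summary.csv")),
                     row.names = FALSE)
    yaml::write_yaml(
      list(kind = spec$kind, means = spec$means, sds = spec$sds,
           variants = spec$variants, n_frozen = spec$n_frozen,
           n_unfrozen = spec$n_unfrozen, duration = spec$duration,
           seed = spec$seed,
           package_version = as.character(utils::packageVersion("analogspike"))),
      file.path(out_dir, paste0(spec$kind, "_provenance.yaml")))
  }
  res
}
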