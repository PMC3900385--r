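# analogspike

Simulation and analysis pipeline for a classic question in computational
neuroscience: **how much information is lost, and how much energy
efficiency sacrificed, when a neuron converts graded (analogue) membrane
potentials into action potentials?**

The package simulates a 100 µm² single-compartment membrane patch with
stochastic squid-type voltage-gated channels and compares four variants —
the spiking model (stochastic Na⁺/K⁺), two channel-swap variants with one
deterministic population, and a graded model lacking Na⁺ channels — under
matched band-limited (300 Hz) Gaussian white-noise current stimuli.

At its core are:

* a **hybrid stochastic Hodgkin–Huxley integrator** (Rcpp): forward Euler
  for the membrane equation
  `Cm dV/dt = I_stim − gNa m³h (V−ENa) − gK n⁴ (V−EK) − gL (V−EL)`
  at 10 µs steps, with channel ensembles advanced by the exact Gillespie
  algorithm over the 13-state / 28-transition Na⁺+K⁺ Markov scheme;
* the **direct method** for spike-train information: binary 1 ms letters,
  word entropies with Treves–Panzeri bias correction, data-size and
  word-length extrapolation, `info = total − noise` entropy rates;
* the **Gaussian-channel bound** for analogue responses:
  `∫ log2(1 + SNR(f)) df` over 0–300 Hz from multitaper signal/noise
  spectra of frozen-noise trials;
* **Wiener-filter stimulus reconstruction** with 65–35 cross-validation,
  coherence information `−∫ log2(1 − γ²(f)) df` and nRMSE;
* **action-potential footprint experiments**: spike excision
  (pseudo-generator potential) and insertion of 6 ms linear
  interpolations into graded responses (deterministic / jittered /
  random schemes, 10–80 per second);
* **ATP accounting**: total K⁺ charge (delayed rectifier + K⁺-permeable
  leak branch) × N_A/(2F), giving bits per ATP molecule.

## Worked example

Twenty one-second frozen trials of the graded model at the
low-mean/high-SD stimulus corner, and the spiking model's direct-method
information on the same stimulus:

```r
library(analogspike)

run_g <- run_condition("graded", stim_mean = 1, stim_sd = 10,
                       n_frozen = 20, n_unfrozen = 0, seed = 5)
analog_info(sapply(run_g$frozen, `[[`, "v"), dt = 1e-5)
#> <analog_info> 2090.6 bits/s over 0-300 Hz (20 trials)

run_s <- run_condition("spiking", 1, 10, n_frozen = 20, n_unfrozen = 20,
                       seed = 7)
est <- direct_method_info(lapply(run_s$frozen, detect_spikes),
                          lapply(run_s$unfrozen, detect_spikes),
                          duration = 1)
est
#> <entropy_estimate> total 248.0, noise 51.0, info 197.1 bits/s (20/20 trials)
```

The graded membrane carries roughly an order of magnitude more
information than the spike train evoked by the same stimulus; excising
the spikes (`pseudo_generator()`) yields an intermediate rate, and
`energy_report()` shows the spike train also costs roughly an order of
magnitude more ATP per second — the two-fold penalty of going digital.

`run_experiment(experiment_spec(...))` orchestrates whole stimulus grids
and writes tidy CSV summaries; results carry `tidy()`/`glance()` methods
and `autoplot()` diagnostics throughout.

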