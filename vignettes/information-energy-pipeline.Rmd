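---
title: "Quantifying information loss and energy cost in the graded-to-spike conversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying information loss and energy cost in the graded-to-spike conversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(analogspike)
```

## The scientific question

Neurons carry information both as continuous (graded, analogue) membrane
potentials and as discrete action potentials. The conversion from
analogue to pulsatile coding loses information and costs energy.
`analogspike` simulates a 100 µm² single-compartment membrane patch with
squid-type voltage-gated Na⁺ and K⁺ channels and quantifies, for matched
current stimuli:

* how many bits/s a spike train carries (direct-method entropy of binary
  spike words),
* how many bits/s the analogue voltage carries (Gaussian-channel bound
  from signal and noise spectra),
* how well a linear decoder can reconstruct the stimulus (Wiener
  filtering, coherence information, nRMSE),
* how much of the analogue signal is obscured by the finite width of each
  action potential (the 6 ms "footprint"),
* and how many ATP molecules the Na⁺/K⁺ pump must hydrolyse to support
  each coding regime (bits per ATP).

Four model variants are compared: the spiking model (stochastic Na⁺ and
K⁺ channels), two channel-swap variants in which one population is made
deterministic, and the graded model, which lacks Na⁺ channels entirely.

## The biophysical model

The membrane obeys the current-balance equation

$$C_m \frac{dV}{dt} = I_{stim}(t) + I_{noise}(t)
  - \bar g_{Na} p_{Na}(t)\,(V - E_{Na})
  - \bar g_K p_K(t)\,(V - E_K)
  - g_L (V - E_L),$$

with $p_{Na}$, $p_K$ the open fractions of the two channel populations.
Deterministic populations follow the classical gating ODEs
$\dot x = \alpha_x(V)(1 - x) - \beta_x(V) x$ with $p_{Na} = m^3 h$ and
$p_K = n^4$. Stochastic populations are finite Markov ensembles: the Na⁺
channel occupies the 8-state $m_i h_j$ lattice (20 transitions,
conducting state $m_3 h_1$), the K⁺ channel the 5-state $n_i$ chain
(8 transitions, conducting state $n_4$) — 13 states and 28 transitions in
all. Within each 10 µs integration step the transition rates are frozen
at the step's voltage and the ensemble is advanced by the exact Gillespie
algorithm: exponential waiting times at total propensity
$\lambda = \sum_j a_j$ (rate × source occupancy), transitions selected
with probability $a_j/\lambda$. Voltage and deterministic gates use
forward Euler; this hybrid
(exact jumps within frozen-rate windows) is the standard approach when
the voltage moves little per step, which a 10 µs step guarantees.

### Parameters

| quantity | value | unit |
|---|---|---|
| $C_m$ | 1 | µF/cm² |
| $\bar g_{Na}$, $\bar g_K$, $g_L$ | 120, 36, 0.3 | mS/cm² |
| $E_{Na}$, $E_K$, $E_L$ | 50, −77, −54.4 | mV |
| area | 100 | µm² |
| $N_{Na}$, $N_K$ | 6000, 1800 | channels |
| integration step | 10 | µs |

The package uses the canonical squid-axon parameter set in the modern
voltage convention, with the standard channel densities (60 Na⁺/µm²,
18 K⁺/µm², i.e. 20 pS single channels). Kinetic variants of this model
family exist in which the spike threshold under slow depolarisation lies
near −68 mV; with the canonical set it sits near −60 mV, which matters
for one result discussed under *Limitations*. All
parameters live in `biophys_params()` and can be swapped wholesale
(`write_params_yaml()` / `read_params_yaml()` provide a file format).

```{r rates}
gating_rates(-40)$alpha_m   # removable singularity, evaluated by limit
resting_potential()         # full model
resting_potential(na_present = FALSE)  # graded (Na-free) model
```

## The stimulus generator

All inputs are synthesised: there is no external data. The generator
(`band_limited_noise()`) draws Gaussian white noise at the simulation
rate, low-passes it at 300 Hz with an order-40 Butterworth filter and
rescales to the requested mean and SD (1–10 µA/cm² across the experiment
grids). The filter is realised as 20 second-order sections computed from
the analytic Butterworth pole positions — a single order-40 transfer
function is numerically unusable — and a 50 ms lead-in absorbs the causal
transient. Variance is rescaled after filtering, so the configured SD is
the SD delivered to the membrane.

Two session types mirror the experimental design: *frozen* sessions
repeat one realisation (exposing trial-to-trial noise; used for noise
entropy and for the signal/noise split), *unfrozen* sessions draw
independent realisations (used for total entropy and for Wiener
decoding). Extrinsic noise, when requested, is unfiltered broadband
Gaussian noise with variance $\sigma_{signal}^2/\Omega$, regenerated per
trial even under frozen signals. Trials default to 1 s at 10 µs
resolution, 60 per session at full scale.

What the generator does *not* emulate: naturalistic (non-Gaussian,
long-correlation) stimulus statistics, conductance-based synaptic input,
and any spatial structure. Conclusions drawn from the tests therefore
concern this stimulus family only.

## Information estimators

**Spike trains (direct method).** Spikes are detected as upward
crossings of −20 mV with a 2 ms dead time (unambiguous for ~100 mV
spikes), binned into 1 ms binary letters and grouped into words of
K ∈ {2, 4, 6, 8, 12, 16, 24, 32, 48, 64} letters. Total entropy comes
from the pooled word distribution of unfrozen trials, noise entropy from
per-time-slice distributions across frozen trials. Each plug-in entropy
receives the first-order Treves–Panzeri correction
$(R_{occ} - 1)/(2N\ln 2)$, and each per-K rate is additionally
extrapolated to infinite data size from nested trial subsets (all, 1/2,
1/4 of trials, linear in inverse trial count) — without this step the
undersampled noise words bias the information up by tens of bits/s.
Finally each entropy-rate-versus-1/T curve is extrapolated to infinite
word length by a linear fit over the contiguous four-point subset with
the smallest RMS residual, a deterministic reading of "the four most
linear values". Information is the difference of the two intercepts,
clamped at zero (the raw value is kept alongside).

**Analogue responses (Gaussian-channel bound).** From frozen trials the
signal is the pointwise trial mean and the noise the per-trial residual.
Spectra are estimated with a sine-taper multitaper estimator (5 tapers;
the taper family has closed form and behaves like the conventional
NW = 3 Slepian choice), and the bound is
$\int_0^{300} \log_2(1 + SNR(f))\,df$ by the trapezoidal rule. It is an
upper bound: it assumes additive Gaussian signal and noise, which the
graded responses approximate.

**Linear decoding (Wiener/coherence).** Unfrozen sessions provide
(stimulus, response) pairs; the reverse filter
$\langle S R^*\rangle / \langle R R^*\rangle$ is fitted on the first 65%
of trials and evaluated on the rest. Coherence between true and
reconstructed stimulus integrates to the coherence information
$-\int_0^{300}\log_2(1 - \gamma^2(f))\,df$; nRMSE is the RMS
reconstruction error over the stimulus SD. Spike-train decoding uses the
raw 0/1 indicator vectors at 10 µs — the filter itself performs any
smoothing.

## Footprints and the pseudo-generator potential

`pseudo_generator()` excises each detected spike by replacing the window
from 1 ms before to 5 ms after the threshold crossing (6 ms, the maximum
action-potential width) with a straight line; overlapping windows merge.
The anchoring ahead of the crossing removes the upstroke; it is
configurable.

`insert_footprints()` mimics footprints in graded responses with three
placement schemes: *deterministic* (identical positions in every trial),
*jittered* (a deterministic base grid plus up to ±4 ms of jitter) and
*random* (independent admissible positions per trial). Base positions
keep pairwise start gaps ≥ 10 ms; admissible configurations are sampled
uniformly by the shifted-order-statistics construction, which stays
efficient even at 80 insertions/s where naive rejection stalls. Jitter
is drawn once and shared across trials: per-trial jitter converts signal
into trial-to-trial noise and demonstrably halves the Gaussian-channel
information, contradicting the empirical finding that jittered insertion
leaves it unchanged — sharing the draw reproduces the full pattern
(deterministic/jittered neutral for the SNR-based bound, all three
schemes equally damaging for coherence). After jitter, windows are
re-checked for overlap and violating draws resampled.

The footprint information loss is reported as the matched-stimulus
deficit relative to the uninterpolated baseline,
$100\,(B_0 - B_{matched})/B_0$: interpolating stimulus and response at
identical positions isolates what the footprint truly blanks out from
what mere stimulus/response mismatch destroys.

## Energy accounting

The Na⁺/K⁺ pump imports 2 K⁺ per ATP, so ATP/s is the integrated total
K⁺ charge divided by $2e$ (equivalently multiplied by $N_A/2F$). The
total K⁺ current is the delayed-rectifier current plus a K⁺-permeable
leak branch obtained by splitting $g_L$ into K⁺ and Na⁺ branches under
the two constraints that conductances sum to $g_L$ and the branch
currents reproduce the leak current at every voltage — the unique linear
solution gives $g_{L,K} = 0.2466$ mS/cm². The signed integral is the
default (inward K⁺ flux at $V < E_K$ reduces pump load); a rectified
mode is provided. Pseudo-generator energy re-derives the K⁺ current from
the interpolated voltage with deterministic n-gating, since the original
channel states are meaningless inside an excised window. Stoichiometry
on analytic currents is exact to machine precision.

## Numerical choices and degenerate inputs

* Initial conditions: voltage at the variant's resting potential,
  stochastic occupancies drawn from the clamped-voltage equilibrium;
  100 ms of burn-in at the stimulus mean is discarded.
* Holding currents are found by bisection on 2 s simulations (200 ms
  burn-in) to a 0.5 mV tolerance; sustained spiking aborts the search.
* Zero total propensity leaves Gillespie occupancies unchanged; a zero-SD
  stimulus is a constant trace; coherence values numerically above 1 are
  clipped to $1 - 10^{-12}$ with a warning.
* Seeds: every user-facing generator takes a master seed; per-trial child
  seeds are drawn deterministically from it, so identical configurations
  reproduce bit-identically.

## Problem sizes

The full protocol (60 × 1 s trials per session) is what the "paper"
preset runs. The package's tests and the reproduction script use the
"desk" preset — 20 × 1 s trials, with 10 trials for firing-rate means —
which keeps a full reproduction around five minutes on one core while
widening estimator scatter to roughly the ±10–20% range; the headline
quantities are compared at ±25%. Property-style tests use shorter traces
(0.1–0.5 s) wherever a closed form is being checked rather than a
headline value reproduced.

## Known limitations

* With the canonical kinetics the spike threshold sits near −60 mV, so a
  −70 mV holding potential leaves a ~10 mV safety margin and the
  sub-threshold Na⁺ noise there is comparatively weak. Parameter sets
  with a threshold near −68 mV would amplify that noise strongly. As a
  consequence the sub-threshold information of the *spiking* variant at
  −70 mV is high and bimodal across seeds (it halves when a rare
  stochastic spike intrudes into a frozen session). The orderings across
  variants and holding potentials are robust to this.
* The Gaussian-channel bound is reported without entropy-power
  corrections for non-Gaussian noise.
* Only K⁺-coupled pump load is accounted; Ca²⁺/Cl⁻ fluxes and
  housekeeping costs are out of scope, as are conductance stimuli,
  multi-compartment geometry and Q10 temperature scaling.

## A worked run

```{r worked, eval = FALSE}
# graded vs spiking information at the low-mean/high-SD corner (desk scale)
run_g <- run_condition("graded", stim_mean = 1, stim_sd = 10,
                       n_frozen = 20, n_unfrozen = 0, seed = 5)
analog_info(sapply(run_g$frozen, `[[`, "v"), dt = 1e-5)$info
#> ~2100 bits/s

run_s <- run_condition("spiking", 1, 10, n_frozen = 20, n_unfrozen = 20,
                       seed = 7)
direct_method_info(lapply(run_s$frozen, detect_spikes),
                   lapply(run_s$unfrozen, detect_spikes), duration = 1)
#> info ~200 bits/s

# the whole headline set in one call (~4-5 min)
reproduce_headline_results(seed = 1, n_trials = 20)
```
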