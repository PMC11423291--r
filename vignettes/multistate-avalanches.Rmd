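---
title: "Avalanche criticality in up and down states: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Avalanche criticality in up and down states: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(avalanchr)
```

## The scientific problem

Dissociated neuronal cultures (and cortical/hippocampal tissue during sleep
or anesthesia) alternate between two regimes: brief *up states* — network
bursts in which most neurons fire at high rate — and long *down states* of
sparse, noise-driven activity. A long-standing hypothesis holds that the
high-activity regime sits at a critical point (scale-free cascade
statistics) while the low-activity regime is subcritical. Testing this
requires analyzing the cascade statistics — *neuronal avalanches* — of the
two states separately, each at its own intrinsic time scale.

An avalanche is the maximal run of consecutive time bins that each contain
at least one spike from the observed population, bounded by empty bins; its
size $S$ is the total spike count and its duration $T$ the number of bins.
At criticality the mean-field branching-process laws are

$$P(S) \sim S^{-\tau}, \qquad P(T) \sim T^{-\alpha}, \qquad
  \langle T \rangle(S) \sim S^{\gamma},$$

with $\tau = 3/2$, $\alpha = 2$, $\gamma = 1/2$, and the exponents are
constrained by $(\alpha - 1)/(\tau - 1) = 1/\gamma$ whether or not they take
mean-field values.

Because the avalanche definition depends on the bin width, the package
treats the bin width like a finite-size scaling variable: distributions
measured at different bin widths are collapsed via

$$P(S) \sim S^{-\tau} f\!\left(S / \mathrm{bin}^{\beta_S}\right)$$

(power-law family), or, for exponential-like statistics ($\tau = 0$), via
$P(S)\,\mathrm{bin}^{\beta_S}$ versus $S/\mathrm{bin}^{\beta_S}$. The
bin-scaling exponents obey $\beta_T = \gamma\,\beta_S$. This machinery is
what turns the bin-width nuisance into a second, independent
characterization of the dynamics.

## Pipeline overview

`run_full_analysis()` chains the stages; each is exported on its own:

1. `bin_raster()` + `population_rate()`: per-frame population rate,
   normalized per neuron (silent neurons stay in the denominator).
2. `smooth_rate()`: Gaussian kernel, $\sigma$ = 5 frames for 200 fps
   recordings and 20 frames for simulated rasters (sub-ms steps); unit-sum
   kernel truncated at $\pm 4\sigma$, reflected boundaries.
3. `schmitt_segment()`: hysteretic two-threshold segmentation, upper
   threshold $10^{-3}$ and lower $3\times10^{-4}$ spikes/frame/neuron, the
   same for recordings and simulations. The trigger starts in the down
   state; strict inequalities switch states, ties and in-band values keep
   the current state. Leading/trailing (censored) intervals are kept in
   the segmentation but excluded from duration statistics.
4. `restrict_to_state()` + `sample_patches()` + `state_avalanches()`:
   per-state avalanche detection. Bin grids restart at every state
   interval, so an avalanche never spans a state transition. Patch
   subsampling (100 random patches of 50% of the neurons, following the
   field-of-view emulation used for this preparation) pools avalanches
   into one ensemble per bin width.
5. `empirical_pdf()` + `collapse_power_law()` / `collapse_exponential()`:
   log-binned distributions per bin width and the scaling collapse.
6. `fit_power_law_range()` + `ks_pvalue()`: extended-range power-law
   validation; a state is labeled `power_law` when any bin width of its
   grid admits an extended range passing the p-value gate (p > 0.1),
   `exponential_like` otherwise.
7. `mean_duration_vs_size()`: $\gamma$ per bin width, combined across the
   grid by inverse variance (the relation $\beta_T = \gamma\beta_S$
   presumes one $\gamma$).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| Schmitt upper / lower | 1e-3 / 3e-4 | spikes/frame/neuron | separates burst onsets from single-cell noise in populations of ~600-1500 neurons |
| smoothing $\sigma$ | 5 (exp) / 20 (sim) frames | frames | matches burst rise times at 5 ms and 0.1 ms frames respectively |
| up-state bin grid | {1,2,4,8,16,32} x frame | s | glutamatergic transmission time scale (ms); collapse needs several octaves |
| down-state bin grid | {64,...,2048} x frame (sim), {8,...,128} x frame (exp) | s | the down state's interspike interval is 5-10x longer; avalanches only emerge at tens-hundreds of ms bins |
| patches | 100 x 50% | - | enlarges the avalanche ensemble and decorrelates the KS p-value iterations |
| p gate | 0.1 | - | conventional "reasonably high" goodness-of-fit bar |
| collapse grids | $\tau \in [1, 2.5]$, $\beta \in [0, 3]$, step 0.05 | - | covers all exponent values reported for this preparation with margin |

The collapse quality is the weighted mean squared vertical log-dispersion
between the rescaled curves on their common support, with weights
increasing linearly toward the large-argument side — a quantitative
implementation of the usual by-eye criterion that the curves must align on
the right-hand side of the plot. The quoted uncertainty is half the grid
extent over which the quality stays within 5% of its minimum.

### Integer data and the KS gate

Avalanche sizes and durations are integers, while the fitted model is the
continuous truncated power law (the closed-form p-value series is the
continuous-KS formula). The discreteness error is a CDF step of order
$p(x_{\min})$, which the range search automatically escapes by moving
$x_{\min}$ up a decade or so. Because the continuous p-value at pooled
sample sizes of $10^5$-$10^6$ would reject *any* model for microscopic
discreteness, the gate follows the iteration scheme used for patch
ensembles: p is computed on random subsamples of at most 2,500 in-range
values (the order of one patch's avalanche count) and the mean over
iterations is gated — 20 iterations during the range scan, 100 for the
final reported mean ± SEM.

## The synthetic-data generators

### Critical branching process

`branching_process()` draws Galton-Watson avalanches with Poisson
offspring (mean `m`); sizes and durations are simulated exactly through
the generation totals. At `m = 1` it is the mean-field reference: the
pipeline's fitting stages must recover $\tau = 1.5$, $\alpha = 2.0$,
$\gamma = 0.5$ from it, which is the package's primary correctness oracle
for the estimation chain. Generations are capped (default $10^4$) and
capped avalanches are flagged; the $\gamma$ estimator excludes size
classes below $S = 10$, where lattice corrections to
$\langle T\rangle(S)$ are visible, and classes with fewer than 10
avalanches.

### Culture network model

`culture_network()` + `simulate_culture()` implement a spatially embedded
network of quadratic integrate-and-fire neurons with adaptation:

$$C\dot v = k (v - v_r)(v - v_t) - u + I + I_0 + \eta, \qquad
  \tau_a \dot u = b (v - v_r) - u,$$

with spike reset $v \to v_c$, $u \to u + d$ at $v \ge v_p$. Each spike of
neuron $i$ delivers an exponentially decaying current $g\,D_i$ to its
targets, where the short-term depression variable obeys
$\dot D = (1 - D)/\tau_D$ between spikes and $D \to \beta D$ at each
presynaptic spike ($\tau_D$ = 2 s / 0.2 s and $\beta$ = 0.8 / 0.95 for
excitatory/inhibitory cells). Spontaneous activity comes from miniature
synaptic currents — a Poisson process (rate 0.1 per ms) of 30 mV kicks
decaying with 10 ms — plus white membrane noise. These parameters produce
an isolated-neuron spontaneous rate of order 0.1 Hz.

Short-term depression is the engine of bistability: a nucleating burst
exhausts $D$ across the population (up-to-down transition), and the slow
recovery ($\tau_D$ = 2 s for excitation) sets the refractory time scale of
the down state, giving the quasi-periodic alternation and
$\langle T_{\rm down}\rangle \gg \langle T_{\rm up}\rangle$.

Connectivity is geometric: neurons at density 800 /mm², axons grown as
biased random walks (10 µm segments, heading sd 15°), total length
Rayleigh-distributed with scale 900 µm (mean ≈ 1.1 mm — the scale of real
axons in culture; note that reading the distribution's literal variance as
900 µm² would give 60 µm axons and an unconnected network, so the value is
interpreted as the squared scale parameter), dendritic disks with Gaussian
radius (150 ± 40 µm, truncated at 10 µm), and a connection with
probability 0.13 wherever an axon crosses a disk (at most one synapse per
ordered pair). 20% of neurons are inhibitory. Variants: `heterogeneous`
(70% standard excitatory, 10% bursty with $v_c = -40$, $d = 50$; all
excitatory $v_r = -62$ mV + Rayleigh offset) and `inhibition_blocked`
(inhibitory strength zeroed — the in-silico analogue of saturating
picrotoxin).

### Numerical choices

* Forward Euler at $dt = 0.1$ ms, double precision, guard at
  $|v| > 10^3$ mV.
* White noise enters as $\eta = g_s \sqrt{2/dt}\,\xi$ per step
  (Euler-Maruyama discretization of
  $\langle\eta(t)\eta(t')\rangle = 2 g_s \delta(t - t')$).
* Minis share one exponentially decaying accumulator per neuron (the
  parsimonious reading of a single spontaneous-release current $I_0$).
* Synaptic delivery is instantaneous (no axonal delays are specified for
  this model class); all synchronous spikes of a step are delivered after
  the step's integration sweep.
* The firing cutoff and reset of standard cells, $v_p = +30$ mV and
  $v_c = -50$ mV, follow the usual convention for this neuron class; the
  bursty override ($v_c = -40$) only makes sense against such a baseline.
* Simulations are reproducible from one integer seed via a dedicated
  xoshiro256++ stream, independent of R's global RNG.

### The scaled-down operating point

The full-scale model (10 x 10 mm, 80,000 neurons, 1 h) is available but
impractical on a desktop; the package's working configuration is a
2.5 x 2.5 mm region at the same density (5,000 neurons) simulated for
600 s, analyzed within a central circular patch of 0.5 mm radius
(600-700 neurons, comparable to an experimental field of view). Two
compensations restore the bulk dynamics in the small box, both fixed once
as the package defaults:

* **Periodic boundaries.** With 1.1 mm axons, an open 2.5 mm box is all
  edge: every neuron loses afferents and burst nucleation becomes too
  rare. Periodic boundaries emulate the bulk of the large culture (mean
  out-degree ≈ 39 versus ≈ 31 open / ≈ 40 full-scale bulk).
* **Excitatory strength g_exc = 55 mV** (versus ≈ 40 mV at full scale).
  The excitatory strength is the model's control parameter for the
  interval between up states; at reduced scale it must be raised to
  restore quasi-periodic alternation. g = 55 gives inter-burst intervals
  of ~5-10 s and up states of ~0.1 s, reproducing
  $\langle T_{\rm down}\rangle \gg \langle T_{\rm up}\rangle$.

What the scaled-down run preserves: up/down alternation statistics,
robustly exponential-like down states, up-state duration exponents near
$\alpha \approx 1.8$-$1.9$, and up-state size-duration scaling
$\gamma$ in the 0.70-0.82 range around the full-scale 0.75 (seed to
seed). What it cannot fully preserve: the number of decades of scaling —
bursts engulf the small box in ~0.1 s, so size distributions span only
~2 decades and the up-state power-law gate hovers around its threshold
(some seeds are classified power-law, some exponential-like), whereas
the full-scale model is unambiguously power-law in the up state.

## What the generators do and do not emulate

The synthetic rasters emulate: quasi-periodic up/down alternation;
up-state per-neuron interspike intervals far shorter than down-state ones;
populations of hundreds to ~1,500 observed neurons; power-law up-state and
exponential-like down-state avalanche statistics (the model class
reproduces the subcritical-down-state picture — by design it does *not*
reproduce the critical down states observed in real cultures, which is
precisely the discrepancy that makes the model scientifically
interesting). They do not emulate: calcium-indicator dynamics or spike
inference errors, photobleaching drift, spatial inhomogeneity of real
platings, or glial modulation.

Consequently, a passing test suite shows that the *pipeline* measures
exponents correctly on data with known structure and that the *model*
reproduces the documented simulation phenomenology; it cannot by itself
certify conclusions about new experimental recordings.

## Degenerate inputs and edge cases

* Empty rasters, states with no intervals, and neurons with fewer than
  two in-state spikes degrade to warnings + empty summaries, never errors.
* Distributions with fewer than two distinct values refuse to build
  (`empirical_pdf()`), and collapses require three or more bin widths
  with common rescaled support.
* `ks_pvalue()` switches to the dual theta-series below argument 1, where
  the alternating series converges too slowly, and clamps to [0, 1].
* Ties in the Schmitt trigger (values exactly at a threshold) never
  toggle the state, so exact-threshold plateaus are stable.

## Problem sizes

The test suite and the acceptance script use: $10^6$ branching avalanches
(generation cap $10^4$); one 5,000-neuron, 600 s culture simulation;
Monte-Carlo KS nulls of 2,000 replicates at n ∈ {50, 200, 1000}; and
collapse grids of ~1,900 exponent pairs. These sizes were chosen so the
statistical uncertainties of the recovered exponents are comfortably
inside the acceptance tolerances.

## Known limitations

* The collapse-quality uncertainty band is a heuristic (quality-region
  width), not a bootstrap; it is honest about grid resolution but not
  about sample covariance.
* The extended-range search is a deterministic scan over order-statistic
  candidates; a supplementary-material-grade exhaustive search could find
  slightly wider ranges.
* Whether per-state ISIs should pool intervals across neurons or average
  per-neuron means is ambiguous in the field; the package pools (every
  consecutive same-interval spike pair contributes), which weighs active
  neurons more.
* The exponential-like β collapse is fitted separately for sizes and
  durations; a joint fit would share information but couple their errors.
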