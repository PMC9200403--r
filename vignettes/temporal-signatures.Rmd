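---
title: "Temporal signatures and metastable dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal signatures and metastable dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpikeDynamics)
```

This vignette is the package's account of the science it implements: the
temporal signature of single-neuron spiking (the latency LAT and time
constant TAU of the spike autocorrelogram), the biophysical network models
whose AHP and GABA-B conductances control that signature, the hidden Markov
segmentation of population activity into metastable states, and the
state-substitution perturbation protocol that probes how inhibitory neurons
control transitions between states. It also records the numerical and design
choices a maintainer would want to know, and what the synthetic-data
generators do and do not emulate.

## 1. The temporal signature of a spike train

### Spike-count timescale (scTAU)

The coarse estimator bins spikes in 14 successive 50-ms windows of a 700-ms
pre-event epoch per trial and computes, for each positive lag `k`, the mean
across-trial Pearson correlation between bin pairs `(t, t + k)`
(`spikeCountAutocorrelation()`). A mono-exponential
`R ~ A exp(-t / scTAU) + B` is fitted by nonlinear least squares
(`fitScTau()`), either per unit or pooled over a population by stacking lag
points. This estimator cannot resolve dynamics below its 50-ms bin and fails
to converge on many noisy units, which motivates the spike-time method.

### Spike autocorrelogram (LAT, TAU)

`spikeAutocorrelogram()` computes all forward lagged differences between
spike times up to the 100th order, histograms them in 10/3-ms bins over
(0, 1000] ms, converts counts to a density normalized to peak at 1 (the
scale does not affect LAT or TAU, only the fitted A and B), removes the
first 10 ms (refractory-period contamination), and smooths with loess
(local quadratic regression, span 0.1 of the 297 analyzed bins). The peak
of the smoothed curve defines LAT; the maximum is used except when it falls
on the very first bin, in which case the first local maximum after that bin
is used (flagged degenerate if none exists). A mono-exponential
`A exp(-t / TAU) + B` is then fitted from the peak to the end of the curve
(the GLOBAL fit) with 50 random restarts drawn uniformly in
`[0, 2 (max - min)]` for A, `[0, 2 min]` for B and `[0, 1000]` ms for TAU,
keeping the lowest-residual fit. A fit is valid iff A, B and TAU are all
positive; the 1000-ms range bounds only the initial guesses, because
capping the estimate itself would right-censor the TAU distribution and
bias population medians down for slow units.

A small minority of autocorrelograms show a fast post-peak dip followed by
a second peak (burst-dominated units). A dip is declared when the first
local minimum within 100 ms after the peak descends below
`min + 0.75 (max - min)` of the smoothed curve's global range; the phrase
"below 75% of the global range" admits a second reading (below
`min + 0.25 (max - min)`), which is available through the `dipFraction`
argument. When a dip exists, FAST (peak to dip) and SLOW (second peak to
end) fits are computed purely as a quality check: the GLOBAL fit is kept
when either is invalid or when its RMSE is below the sum of their RMSEs;
otherwise the unit is excluded. Units without a valid GLOBAL fit are
excluded with a reason.

Fits run on the smoothed curve, consistent with the peak and dip logic
operating on it. The minimum spike count for a fit defaults to 1000 within
the analyzed segment (exposed as `minSpikes`); local extrema use strict
one-bin inequalities with plateau ties broken toward the earlier bin.

### Known limitations of the LAT estimator

For renewal trains with weak ISI structure the expected autocorrelogram is
a flat plateau (exactly flat for exponential ISIs), so the global-maximum
peak rule returns a noise-driven latency. The first-order latency
(`firstOrderLatency()`, the mode of the smoothed ISI histogram built with
the same binning) remains sharply identified in that regime and is the
meaningful refractoriness readout there. Recorded cortical units always
carry slow rate fluctuations, which make the autocorrelogram decay and the
global maximum structural, so the degenerate plateau case does not arise on
data of the kind the pipeline targets. Similarly, TAU recovered from a
1000-ms window is biased low when the true timescale approaches the window
(about -15 to -20% at 600 ms in our synthetic batteries), one reason
spike-count timescales (scTAU) tend to exceed autocorrelogram TAU.

## 2. Rank-based statistics

`blomTransform()` implements the rank-based inverse normal transform
`Y_i = qnorm((r_i - 3/8) / (N + 1/4))` with average ranks on ties, making
downstream parametric tests distribution-free in the input. Context
modulation of a unit's timescale between two conditions is summarized by
`modulationIndex()`, the natural-log ratio `log(TAU_a) / log(TAU_b)` (1
means no modulation; which condition is the numerator is an explicit
argument, as the convention is not fixed). `medianSplit()` divides units
into short/long groups at the per-stratum median (exact-median values go to
"short" deterministically) and `permuteSplit()` redraws group labels
preserving group sizes, for permutation nulls of group-difference
statistics.

## 3. Cellular model

A single-compartment Hodgkin-Huxley model of a frontal pyramidal neuron
(`cellularParams()`, `simulateCell()`): leak, spike Na/K currents,
high-threshold calcium (CaL), calcium-gated cationic (CAN) and
after-hyperpolarization potassium (AHP) currents, optional low-threshold
calcium (CaT) and H currents (zero conductance by default), and a
sub-membrane calcium shell with first-order extrusion fed by the calcium
currents, with the shell surface-to-volume ratio of a spherical soma. CAN
and AHP gating follows first-order kinetics with calcium-dependent rates
(`tau = 1/(alpha Ca + beta)`, `p_inf = alpha Ca / (alpha Ca + beta)`), the
loop that generates regenerative (CAN) and refractory (AHP) discharge
patterning.

In-vivo-like input is a stochastic background (`ouBackgroundParams()`,
`configureBackground()`): AMPA, NMDA, GABA-A and GABA-B opening
probabilities follow Ornstein-Uhlenbeck processes whose means equal the
steady states of first-order (AMPA, GABA-A) or second-order (NMDA, GABA-B)
synaptic kinetics driven by 484 excitatory and 121 inhibitory presynaptic
neurons at 7 Hz, with `sigma = m/2`. Inhibitory maximal conductances are
solved from the driving-force balance at the mean potential (-57.5 mV)
with the 4:1 excitatory/inhibitory count ratio. NMDA carries the standard
exponential magnesium-block factor.

Numerical choices, in the package's own words:

* Forward Euler at dt = 0.1 ms; gating clamped to [0, 1]; calcium floored
  at 0; integration aborts with a diagnostic if |V| exceeds 200 mV.
* The OU processes are advanced with the exact discrete OU update (so the
  stationary standard deviation equals the specified sigma) and reflected
  at [0, 1].
* The spike Na/K rate functions use Boltzmann steady states
  (m: -42/5 mV with tau 0.5 ms; h: -50/4 mV, tau 2 ms; n: -45/4 mV, tau
  2 ms). These were chosen so that the model's maximal conductances
  (gNa = 30, gK = 2 mS/cm2) produce full-height spikes with reliable
  repolarization at this time step; classical rate functions built for
  gK near 9 mS/cm2 leave this conductance set in depolarization block.
* The CaL activation time constant follows `10 / (alpha + beta V)` with a
  positivity guard; the defaults (alpha 6, beta 0.1 /mV) make activation
  fast (1-2 ms) at spike voltages and frozen far below threshold, so
  calcium entry is spike-gated and the CAN/AHP adaptation loop engages.
  The half-activation (-20 mV, slope 6 mV) is a standard L-type value.
* Spikes are detected as upward crossings of -20 mV, well inside the
  upstroke; any threshold there is equivalent at dt = 0.1 ms.

Under the default balanced background the cell fires irregularly at around
10-20 Hz (CV near 0.8); grid explorations (`sweepCellular()`) flag
parameter points whose mean rate exceeds 20 Hz as unrealistic and discard
them from similarity analyses.

## 4. Recurrent network model

`networkParams()` builds the 605-neuron conductance-based
leaky-integrate-and-fire network: 484 excitatory and 121 inhibitory
neurons, block-wise sparse connectivity (E->E, E->I, I->I at 0.3, I->E at
0.55), log-normal synaptic weights with mean 0.03 and sd 0.02 (moment
matched; a switch treats the parameters as log-scale instead), no
autapses, and per-postsynaptic-neuron GABA-A/GABA-B conductances solved
from the recurrent balance equations with each neuron's realized
excitatory/inhibitory weight-sum ratio. Excitatory neurons carry CAN and
AHP currents with the cellular kinetics; calcium jumps by 0.2 uM per spike
and decays with 25 ms. First-order AMPA/GABA-A and second-order
NMDA/GABA-B opening dynamics are driven by presynaptic spikes (increment
0.1 toward saturation) and delivered with a uniform 0.5-ms delay (one
integration step, implemented as a pending-spike buffer). A constant AMPA
feed-forward conductance (gAMPAFF x 0.101) stands in for external drive.
Integration is forward Euler at dt = 0.5 ms; threshold -50 mV, reset and
rest -65 mV, 3-ms refractory period. The leak reversal equals the
rest/reset potential (-65 mV), the integrate-and-fire reading of "resting
potential".

Reciprocal E-E motifs: unordered pairs are drawn none / unidirectional /
bidirectional with `P(bidirectional) = rho pEE^2` (rho = 4) while keeping
the marginal density at pEE. At the default pEE = 0.3 the 4x factor is
infeasible (4 x 0.09 > 0.3), so rho is capped at `1/pEE` (full
reciprocity, effective factor 3.33); the exact 4x over-representation is
realized at lower densities and verified in the tests at pEE = 0.2.

The network receives no stochastic input: activity is chaotic, and the
seed only draws the initial membrane potentials. Simulations are therefore
bit-reproducible, and full-state snapshots (`snapshotTimes`) restore the
trajectory exactly, which the perturbation protocol requires. Snapshots
store the derived first-order synaptic sums as well, so resuming is exact
to the last bit; after a perturbation those sums are recomputed from the
substituted opening probabilities.

Area presets fix the conductance couple studied throughout:
LPFCm (gAHP = 0.022, gGABAB = 0.0035 mS/cm2) and MCCm (0.087, 0.0143),
both with gCAN = 0.025, plus the two hybrids (MCCm with the LPFCm gAHP or
gGABAB). Under these presets the network fires asynchronously and
irregularly at a few Hz with ISI CVs near 1, MCCm shows larger excitatory
LAT and larger TAU in both populations than LPFCm, and lowering gAHP alone
moves excitatory LAT while leaving inhibitory LAT essentially unchanged
(AHP is absent from inhibitory neurons) - the trends the acceptance tests
assert on two 300-s simulations per preset.

## 5. Model-data similarity

`bivariateDensity()` estimates the bivariate (TAU, LAT) density of a
population with a normal-kernel KDE on a fixed shared grid (TAU in
[0, 1000] ms, LAT in [0, 300] ms, 200 x 200), normalized to integrate
to 1. Bandwidths follow Scott's rule per dimension (`sd * n^(-1/6)`); the
value of the similarity is bandwidth-dependent, so only relative structure
across a parameter map is interpreted, never absolute values. For cellular
models the similarity to a cortical population is the population's density
at the model's (TAU, LAT) point (`cellularSimilarity()`, with the 20-Hz
realism exclusion); for networks it is the normalized Frobenius inner
product of the two densities (`networkSimilarity()`), combined across
populations as `0.8 S(RS, Exc) + 0.2 S(FS, Inh)` per the cortical
excitatory fraction (`overallSimilarity()`). Best-fit conductances are
read off a similarity map as the similarity-weighted centroid of the
region above 80% of the maximum (`similarityCentroid()`).

## 6. Metastable states

`fitHMM()` segments population spiking into discrete states with an
EM-trained hidden Markov model on binarized 0.5-ms bins. Two emission
families are provided. The default treats each bin as an independent
per-neuron Bernoulli vector - the natural family at bins that hold at most
one spike per neuron. The alternative (`emission = "multinomial"`) is the
classical population-HMM encoding: each bin is represented by the identity
of the spiking neuron, with one spike selected at random when several
neurons fire in the same bin (or a silence symbol). The two differ
materially in how much evidence a bin carries: the multinomial symbol
discards all but one spike, so posteriors commit more slowly, ambiguous
(null-state) episodes last longer, and re-drawing the tie-breaking changes
the decoded states slightly - which is exactly what makes the perturbation
protocol's basal escape/reach rates nonzero under that encoding. The
acceptance script uses the multinomial encoding for the state-duration and
perturbation measurements; the Bernoulli family remains the package
default for recovery analyses, where its sharper posteriors are a virtue. The self-transition prior is initialized from a 300-ms
mean state duration (`p_stay = 1 - bin/300`); emissions start from
per-neuron mean rates perturbed by state-specific log-normal factors, and
the best of `nInits` restarts by log-likelihood is kept (100 restarts were
used for recording-scale data; model rasters need far fewer). EM stops at
a relative log-likelihood change below 1e-6 or 500 iterations. The
forward-backward pass exploits spike sparsity, so 600-s records at 0.5 ms
(1.2 million bins) fit in seconds to minutes. Long fine-binned rasters are
stored sparsely (`Matrix`), which is why `PopulationRaster` accepts both
dense and sparse count matrices.

Decoding (`decodeStates()`) uses posterior marginals, not Viterbi: a bin
belongs to the state whose posterior reaches 0.8, otherwise to the null
state S0; S0 periods flanked by the same state are reattributed to it. The
raw (pre-reattribution) period tiling is kept, since the duration of raw
S0 periods is itself a readout of transition sharpness.
`durationStatistics()` pools period durations across states (excluding
periods beyond 300 s), computes the empirical distribution p(d), the
time-weighted `p_t(d) = p(d) d / sum p(u) u`, the median duration, and the
Kolmogorov-Smirnov distance of log-durations to a fitted normal - the
over-representation measure for short states. `stateGeometry()` smooths
per-neuron rates with a 100-ms Gaussian kernel (evaluated on a 10-ms grid;
finer evaluation adds nothing under a 100-ms kernel), drops neurons below
0.5 Hz, standardizes, and measures the mean pairwise distance between
per-state centroids plus a PCA projection. `hmmModelSelection()` scans
AIC/BIC over 2-10 states (the 4-state default is the parsimonious choice;
the criteria change little over that range), and `shuffleRaster()`
randomizes both spike timing and neuron assignment as the control that
collapses metastable structure.

Pseudo-populations (`buildPseudoPopulation()`) pool units recorded in
different sessions onto a common clock, deliberately discarding
cross-session phase; decoded states are then chimeric combinations of
per-session dynamics but still capture the temporal structure of
collective activity, which is what the LPFC/MCC comparison rests on.

## 7. Perturbation protocol

`preparePerturbation()` simulates a network, fits the HMM, decodes
periods, and re-runs the identical trajectory capturing snapshots 50 ms
after the onset of every period longer than 100 ms. `runPerturbation()`
substitutes the dynamical state (membrane potential, refractory and
pending-spike state, calcium, CAN/AHP gating, all synaptic opening
variables) of a random subset of one population with the values from a
target-state snapshot, resumes to the end of the original ongoing period,
and decodes the segment with the frozen HMM (forward-backward under the
unperturbed model, initialized from the unperturbed posterior at the
perturbation time). Escape is the fraction of segment time outside the
ongoing state; reach the fraction inside the target state; reach never
exceeds escape. Because the resumed simulation is exact, the
fraction-zero control reproduces the unperturbed decoded states, and its
escape/reach rates are the basal probabilities used by
`transitionSweep()` to report offset (`raw - basal`) and normalized
(`(raw - basal)/(1 - basal)`, clipped at 0) curves - the published curves
are basal-corrected, and both variants are emitted because the exact
normalization convention is not fixed by the description.

## 8. Synthetic data: what it does and does not emulate

* `genOuPoisson()`: doubly stochastic Poisson trains whose rate follows an
  OU process (default mean 5 Hz, sd 3 Hz, tau 10-1000 ms), rectified at
  zero with a warning beyond 20% rectification. This gives exponentially
  decaying autocorrelograms with a controllable TAU - the property the
  signature pipeline estimates - but no refractoriness, burstiness, or
  non-stationarity.
* `genRenewalBurst()`: gamma-renewal trains (analytic ISI mode
  `(shape-1) scale`) with optional burst insertions, emulating the
  refractory and bursty structure that sets LAT, but with a flat long-lag
  autocorrelogram (no slow decay).
* `genMarkovRaster()`: hidden Markov population rasters with exponential
  (optionally log-normal) dwell times and per-state Poisson rates, the
  ground truth for HMM recovery; neurons are conditionally independent, so
  within-state correlations of real populations are absent.
* `genSessionEvents()`: self-initiated trial logs with planted pauses of
  at least 60 s, rewards, and a seven-step gauge filling over blocks of
  14/21/28/35 correct trials, for segmentation tests only. Trial timing
  within the session is simplified (fixed trial and inter-trial
  durations).

Passing tests on these generators show that each analysis stage recovers
the structure it is built to measure under its own assumptions; they do
not show robustness to electrode drift, correlated noise, or
non-stationary behaviour of real recordings.

## 9. Problem sizes used by the test-suite and the acceptance script

The package's own validation runs at desk scale: signature-recovery
batteries use 600-s trains (50 replicates per timescale in the acceptance
suite); preset comparisons use two 300-s network simulations per preset
with signatures from a 180-neuron subsample; HMM recovery uses a 600-s,
60-neuron, 4-state raster; the perturbation asymmetry check uses one
200-s MCCm network with 3 period-pair combinations per ordered state
pair. The acceptance script simulates each preset for the full 600 s when
measuring null-state durations, and runs the MCCm perturbation protocol
with 4 combinations per state pair at fractions 0 and 0.02, sampling
ongoing periods up to 20 s long (resuming a period costs simulation time
equal to its remaining length, so rare longer periods are excluded from
sampling). These sizes
were chosen so the whole validation is reproducible on a single CPU in
well under an hour while keeping every estimate's sampling error small
against the tolerances asserted.
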