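---
title: "Modeling tDCS-induced network remodeling with homeostatic structural plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling tDCS-induced network remodeling with homeostatic structural plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Transcranial direct current stimulation (tDCS) delivers a weak constant
current through scalp electrodes. The induced electric field is far too weak
to trigger action potentials, but it polarizes neuronal membranes by
fractions of a millivolt, scaled by the cosine of the angle between the
field and the somato-dendritic axis. `tdcsnet` implements a computational
account of how such a small bias, applied to part of a recurrent network
whose wiring is under homeostatic control, can leave a lasting structural
trace — a *cell assembly* — long after the rate perturbation itself has been
absorbed.

The model has three layers.

**Neurons and network.** Current-based leaky integrate-and-fire (LIF)
point neurons:

$$\tau_m \dot V_i(t) = -V_i(t) + \tau_m \sum_j J_{ij}\, S_j(t - d) + \Delta V(t),$$

with `tau_m` = 10 ms, threshold 20 mV, reset 10 mV, refractory period 2 ms,
and delta-pulse synapses: every arriving spike kicks the membrane by the
synaptic amplitude (`J_E` = 0.1 mV for excitatory, `J_I` = −0.8 mV for
inhibitory synapses). The polarization imposed by the electric field enters
as the membrane bias `delta_V`, applied only to excitatory neurons (their
elongated morphology makes them field-sensitive; compact interneurons are
not). The full-size network has 10,000 excitatory and 2,500 inhibitory
neurons; all connections involving inhibitory neurons are static, drawn
once with 10% probability per ordered pair. Every neuron receives external
Poisson input at 30 kHz through 0.1 mV synapses. The network operates in
the asynchronous-irregular, inhibition-dominated regime.

**Calcium as a rate sensor.** Each excitatory neuron integrates its own
spiking into a calcium trace

$$\dot C(t) = -C(t)/\tau_{Ca} + \beta_{Ca} S(t),$$

with `tau_ca` = 10 s and `beta_ca` = 1e-4. At a steady rate $r$ the trace
fluctuates around $r\,\beta_{Ca}\tau_{Ca}$, so the set point
`eps` = 0.008 corresponds to a target rate of
$\epsilon / (\beta_{Ca}\tau_{Ca}) = 8$ Hz (`target_rate()`).

**Structural plasticity.** Excitatory-to-excitatory synapses are not
plastic in strength; they are created and deleted. Each neuron maintains
continuous counters of presynaptic elements (boutons) and postsynaptic
elements (spines), both growing by the linear homeostatic rule

$$\dot z(t) = \nu\,\bigl(1 - C(t)/\epsilon\bigr).$$

Below the set point a neuron produces elements; above it, elements are
removed and the synapses they were bound in break up, with the partner's
element returned to its free pool. Free boutons and spines across the whole
network are randomly combined into synapses (no autapses; multapses —
multiple contacts per ordered pair — are allowed and common). A network
started with no E–E synapses at all grows, within the standard 750 s growth
period, into an equilibrium in which the population rate sits at the set
point; perturbations of the rate in either direction are absorbed by
rewiring rather than by lasting rate changes.

### The growth-rate unit

The growth rate is quoted in the source literature as $\nu = 0.004$ per
second. Taken literally, a neuron could assemble at most three synaptic
elements during the entire 750 s growth period, while the mean-field
operating point of this network (validated by the simulator itself, and by
a Siegert-type self-consistency calculation) places the 8 Hz equilibrium at
roughly 900–1,000 E–E synapses per neuron — the familiar ~9–10% recurrent
connectivity of this model family. The two statements are consistent only
if the growth rate is read as 0.004 elements per *millisecond*. The package
therefore uses `nu` = 4 elements/s as its default; with it, growth
completes and the set point is reached within the stated 750 s, which is
what the package's own acceptance tests verify.

## Stimulation protocols

A montage is abstracted as a partition of the excitatory population into
groups, each with its own polarization: **uni-group** (a fraction `f_G1`
polarized, the rest untouched), **bi-group** (the remainder polarized with
opposite sign), and **tri-group** (two equal groups of opposite polarity on
an unstimulated background). Repetitive protocols alternate `t1` seconds of
stimulation with `t2` seconds of pause (*on-off*) or of reversed polarity
(*alternating*). Stimulation always starts only after the growth period.
`table4_preset()` catalogues the standard configurations, including the
intensity grids (±0.4, ±0.8, ±1.2 mV), the duty-cycle grid with a total
on-time of 6,000 s, and the three-cycle on-off/alternating comparisons.

The orientation factor $\cos\theta$ appears only in the single-neuron
experiment (`simulate_single_neuron()`); network protocols assign each
group its *effective* polarization directly, since a uniform field and a
fixed orientation per neuron would only rescale the group bias.

## Measurements

* **Firing rates** are spike counts in disjoint 5-s windows, averaged
  arithmetically over group members.
* **Connectivity** between groups is the mean synapse count per ordered
  pair, $\Gamma = n^{-2}\sum_{ij} A_{ij}$ for a block of $n^2$ ordered
  pairs. Within-group blocks keep the $n^2$ denominator, so the excluded
  diagonal biases them *down* by a factor $(1 - 1/|G|)$ relative to
  between-group blocks; this is negligible at full scale but material for
  the small groups of desk-scale runs and is taken into account when
  within- and between-group values are compared.
* **The connectivity integral** $I_G$: because remodeling outlives any
  affordable simulation, the relaxation-phase connectivity change is fitted
  with a sum of three exponentials
  $\Gamma(t) = \sum_k A_k e^{-t/\tau_k}$ and summarized by
  $I_G = \sum_k A_k \tau_k$, the integral of the fitted transient over
  $[0, \infty)$. Amplitude signs are left free (relaxation can overshoot);
  time constants are constrained positive and returned in ascending order.

Triple-exponential fits are notoriously ill-conditioned, so
`fit_triple_exponential()` uses an initialization ladder: candidate time
constants log-spaced over `[1, 1e4]` s, amplitudes obtained by a linear
solve for each candidate triple, and the best starts refined by
Levenberg–Marquardt on (A, log τ). A failed refinement falls back to the
best linear-solve estimate with `converged = FALSE`; a non-decaying trace
is flagged `degenerate` instead of being extrapolated. Time constants are
additionally capped at four times the span of the fitted window
(`tau_max`): a finite noisy trace carries no information about components
much slower than itself, and left unbounded such components absorb
baseline noise and inflate the integral arbitrarily. Integrals of slower
transients are attributed at that horizon, which keeps $I_G$ finite and
comparable across runs of equal design.

## Down-scaling

Desk-scale work cannot use 12,500 neurons for thousands of simulated
seconds, and the interesting quantities here are size-intensive: the set
point is a *rate*, and growth, deletion and recovery time constants are
per-neuron quantities. `network_preset(scale)` therefore shrinks only the
neuron counts. Crucially, it preserves the **per-neuron in-degrees** of the
full network (1,000 E inputs per inhibitory neuron, 250 I inputs per
neuron, realized with static multapses) rather than the connection
*probabilities*. Scaling the probabilities instead would cut the recurrent
inhibition per neuron tenfold at `scale = 0.1`: the unconnected network
would then fire far above 8 Hz, the homeostatic controller — which can only
*add* excitation from an empty E–E matrix — could never pull the rate down,
and no equilibrium at the set point would exist. With fixed in-degrees the
mean and variance of the recurrent input per neuron are preserved, and the
desk-scale network (1,000 E + 250 I) reaches the same operating point as
the full-size one: the package's acceptance suite grows it for 750 s and
finds the excitatory population at 8 Hz within the set-point tolerance,
with the equilibrium E–E in-degree the mean-field calculation predicts.

What down-scaling does *not* preserve: shared-input correlations grow as
neurons share more of their inputs, and group-resolved connectivity blocks
average over quadratically fewer ordered pairs, so block estimates are
noisier by the ratio of group sizes. Property tests on scaled networks
therefore average over independent trials, and compare trial means.

## Numerical choices

* `dt` = 0.1 ms. Membrane decay is propagated *exactly* between events
  (`V ← ΔV + (V − ΔV)e^{−dt/τ_m}`); synaptic and external pulses are applied
  at the end of each step. Grid alignment of the Poisson pulses shifts the
  free-potential mean up by the factor $\frac{dt/\tau_m}{1-e^{-dt/\tau_m}}
  \approx 1.005$ — half a percent, visible only in the free-membrane test
  tolerance.
* Synaptic delay `d` = 1 ms (uniform), implemented as a ring buffer;
  threshold ties break toward spiking; during the refractory period the
  membrane is clamped at the reset value and inputs are discarded.
* External drive is delivered as per-step Poisson *counts* per neuron —
  statistically equivalent to individual event times at delta-synapse
  resolution. The inner loop uses an alias-method sampler and a
  xoshiro256++ generator seeded from R's RNG, so `set.seed()` still makes
  entire experiments bit-reproducible.
* The structural update runs every `dt_struct` = 100 ms: calcium is decayed
  in closed form and incremented per spike, counters advance by the linear
  rule, integer surpluses become free elements, deficits consume free
  elements first and then break randomly chosen bound synapses (a multapse
  loses contacts in proportion to its multiplicity), and all free elements
  are then pooled and paired in one shuffled pass. With `tau_ca` two
  orders of magnitude above the cadence, the discretization error of this
  split is negligible.
* Free elements do not decay while unused. The framework this rule
  descends from allows vacant-element decay; it is deliberately not
  implemented here, and free elements persist until paired or consumed by
  a deficit.
* Runaway guard: very strong stimulation can push the network into a
  high-rate state in which deletion accelerates pathologically.
  `stimulate_network()` aborts with a `tdcsnet_runaway` condition when the
  population rate exceeds a configurable ceiling for a sustained period,
  rather than producing silently meaningless output.

## What the experiments show

The package's test and acceptance suites recompute, at desk scale, the
model's characteristic results:

* a somatic bias of ±0.1 mV — far below threshold — shifts the firing rate
  of a background-driven neuron by more than 10% in either direction;
* a network grown from scratch for 750 s settles at the 8 Hz set point;
* uni-group stimulation deletes synapses of the stimulated group during
  the on-phase and triggers preferential regrowth among stimulated neurons
  afterwards (assembly formation), for either stimulation polarity;
* the connectivity integral $I_G$ grows with stimulation intensity and
  shrinks with the stimulated fraction, and at strong polarization the
  uni-group montage outperforms bi- and tri-group montages;
* repetitive stimulation at matched total on-time outperforms a single
  uninterrupted block, and alternating-polarity cycles of matched overall
  amplitude perform like on-off cycles while weaker alternating cycles
  fall behind.

Each of these is asserted by a test at the scale and trial count stated in
the test itself; the scales were chosen once, as the smallest networks
whose dynamics remain in the asynchronous-irregular regime, and the
durations follow the catalogued protocols with relaxation windows long
enough for the fits to stabilize.

## Limitations

* The model is non-spatial: no electric-field geometry, no
  distance-dependent wiring, no axonal-terminal polarization. Montages are
  *defined* by their group structure, not derived from electrode layouts.
* Synapses are identical delta pulses; there is no functional (weight)
  plasticity, so any facilitation is purely a change in contact counts.
* The homeostatic rule is linear in calcium with a single set point;
  richer growth rules (e.g. Gaussian, with a second fixed point) are out
  of scope.
* Down-scaled runs preserve mean-field drive but not correlation
  structure; quantitative connectivity values at desk scale should be
  compared between conditions of the same run, not against full-scale
  absolute values.
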