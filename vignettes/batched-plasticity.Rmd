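---
title: "Batched synaptic plasticity: model, rules and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Batched synaptic plasticity: model, rules and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the model it implements:
the decoupled neural/plasticity architecture, the three learning rules,
the synthetic stimuli, the numerical conventions, and — importantly —
the calibration decisions taken where the underlying experimental
protocols leave parameters open, together with what a passing test does
and does not establish.

## 1. The simulation model

**Neurons.** Current-based leaky integrate-and-fire:
\[
\tau_m \frac{dv}{dt} = -(v - v_{rest}) + r_m\,(i_{syn}(t) + i_{offset}),
\qquad
\tau_{syn} \frac{di_{syn}}{dt} = -i_{syn},
\]
with threshold \(v_{thresh}\), reset \(v_{reset}\) and an absolute
refractory clamp of `t_refrac` ms. Each presynaptic spike adds its
weight (nA) to the synaptic current at its arrival millisecond.
Excitatory and inhibitory inputs are accumulated in separate ring-buffer
lanes but share \(\tau_{syn}\). The 1 ms update uses the *exact*
propagator of this linear system (not Euler), so sub-threshold behaviour
matches the closed form at machine precision; this is also what makes
the "n spikes just reach threshold" weight calibration
(`calibrate_weight()`) a construction rather than a tuned number.
Defaults: \(v_{rest} = v_{reset} = -65\) mV, \(v_{thresh} = -50\) mV,
\(\tau_m = 20\) ms, \(\tau_{syn} = 5\) ms, \(r_m = 1\) MΩ,
`t_refrac` = 2 ms — all overridable per population.

**Delays** are integer milliseconds, minimum 1 (a zero-delay synapse is
disallowed to keep causality explicit) and are reintroduced at the
postsynaptic end: a spike emitted at \(t\) lands in the target's input
slot \(t + d\). Within a step the order is fixed: scheduled source
spikes are emitted and delivered, the current slot is consumed, then
neurons are updated — so an input arriving at \(t\) can contribute to a
spike emitted at \(t\).

**Windows.** Spikes are condensed into bitmaps with 2 ms bins over
128 ms windows (both configurable). Windows are half-open
\([k\cdot128, (k+1)\cdot128)\): a spike exactly on a boundary belongs to
the new window. Multiple spikes in one bin collapse to one set bit; the
postsynaptic spike *counter* used by the rate-based rule is exact
(uncollapsed), as is the per-bin multiplicity used by the calcium trace.
Spike times are reconstructed at bin centres.

**Double buffering and serialisation.** In the hardware-inspired
architecture the neural process records into the current window while a
separate plasticity process consumes the previous one. Here the two are
serialised: at each boundary the batched pass for the window that just
closed runs before recording continues. The reader/writer contract — the
pass sees exactly one completed window, never the one being recorded —
is preserved and tested; true concurrency is not modelled. A run whose
duration is not a multiple of the window span ends with a pass over the
partial final window.

**Write-back accounting.** Every pass visits every row of a plastic
projection exactly once, independent of activity (rules with relaxation
terms — BCM's decay, the bistable drift — change weights even for empty
windows, so rows cannot be skipped). The ledger counts one write-back
per row per pass (batched mode) and, for comparison, one per presynaptic
spike (the cost of a deferred, per-pre-spike update scheme). Over
1000 ms with boundaries at multiples of 128 ms this gives 8 batched
write-backs per row versus 24 for a row whose presynaptic neuron fires
at 24 Hz.

## 2. Trace-based STDP

All-to-all pairing: the total update is
\(\sum_{pairs} F\big((t_{pre}+d) - t_{post}\big)\) with the
double-exponential \(F\). Rather than enumerating pairs, each *synapse*
carries an exponential trace of its arrival times (presynaptic bin
centres shifted by that synapse's delay) and each postsynaptic neuron a
trace of its (collapsed, bin-centre) spikes. At every postsynaptic spike
the weight grows by \(A_+\) times the arrival trace (pairs with
\(\Delta t < 0\)); at every arrival it shrinks by \(A_-\) times the
postsynaptic trace (pairs with \(\Delta t \ge 0\); a coincident pair is
depression, \(F(0) = -A_-\)). Traces are advanced with the exact
exponential solution and carry over across windows.

Two consequences of handling the delay honestly:

- a per-neuron presynaptic trace would be wrong whenever delays differ
  within a row, which is why the trace lives on the synapse;
- an arrival can fall beyond the end of the window that recorded the
  spike (large \(d\)). Such arrivals are *deferred* to the pass that owns
  their arrival time, when the matching postsynaptic history exists.
  With deferral the batched result equals the brute-force all-pairs sum
  exactly (tested to \(10^{-9}\) relative over random spike sets with
  delays up to 40 ms; observed agreement is at machine precision). The
  hardware-inspired scheme leaves this boundary case ambiguous; we chose
  exactness over emulating any particular truncation.

Weight changes accumulate over the window and are clipped to
\([w_{min}, w_{max}]\) once per pass. Pairing is additive
(weight-independent); nearest-neighbour and multiplicative variants are
out of scope.

## 3. BCM

Per window of length \(\Delta t\) (in seconds):
\[
\Delta w = \big[r_{post}(r_{post} - \theta)\, r_{pre}\big]\,\delta\,
\Delta t - \epsilon\, w\, \Delta t .
\]
The presynaptic window rate is read from the (collapsed) bitmap — at the
rates used here bin collapse is negligible — and the postsynaptic rate
from the exact counter. Both are passed through a single-pole low-pass
filter with coefficient `rate_lp` per window (the filter form is a
design choice; the underlying description only asks for "a low-pass
filtered version of the rate"). After the weight update, θ slides:
\(\theta \leftarrow (1-\lambda)\theta + \lambda\, r_{post}\) with the
*instantaneous* window rate as input and `theta_ema` = \(\lambda\).

The initial θ is configurable (`theta0`). The default (first window's
measured rate) is the obvious neutral choice, but a freshly initialised
network measures a near-zero rate, and a near-zero θ makes the first
seconds potentiate everything indiscriminately while the moving average
warms up. The experiments therefore set `theta0` near the expected
initial response rate, which starts the rule at equilibrium.

With θ frozen and stationary rates the rule has the closed-form fixed
point \(w^\ast = \delta\, r_{post}(r_{post}-\theta) r_{pre} / \epsilon\),
and with a stationary postsynaptic rate θ converges to that rate —
both are tested properties.

## 4. Voltage-gated bistable STDP

Postsynaptic spikes feed a calcium trace (\(+J_C\) per spike, decay
\(\tau_C\); coincident spikes add). The neural loop records a 1 ms
bitmap of \(V(t) > \theta_V\); the bit an arrival sees is the membrane
value at the *start* of the arrival millisecond — the potential "at the
time of arrival", before the arrival's own charge and any same-step
reset. At each presynaptic arrival: \(+a\) if the bit is set and
\(C \in [\theta^h_{down}, \theta^h_{up})\); \(-b\) if the bit is clear
and \(C \in [\theta^l_{down}, \theta^l_{up})\); otherwise nothing.
Drift is integrated once per window over its full span with the branch
chosen by the *window-start* weight (\(+\alpha\) above \(\theta_W\),
\(-\beta\) at or below it — the boundary uses the down branch),
jumps being treated as instantaneous. This is an approximation of the
continuous dynamics: a jump that crosses \(\theta_W\) mid-window only
changes the drift branch at the next boundary. Deferred arrivals reuse
the mechanism of the STDP pass and are gated by the bitmap of the window
that owns them. Weights are clipped to \([w_{min}, w_{max}]\) per pass;
with no eligible events the weight converges monotonically to whichever
bound its side of \(\theta_W\) dictates, at the analytically predicted
pass (tested).

## 5. Synthetic stimuli — what they emulate, what they do not

All generators are pure functions of their parameters and a seed.
Poisson sources use per-millisecond Bernoulli thinning
(\(p = rate/1000\), capped with a warning), sampled equivalently as a
binomial count with uniform slot placement; at most one spike per source
per millisecond, matching the engine resolution. Teacher protocols emit
350 Hz/20 ms bursts with a configurable lag. Oriented bars are
rasterised on a 16×16 grid by rotating pixel centres into the bar frame
(symmetric box test with nearest-pixel rounding, so a 180° rotation
preserves the pixel set; cardinal bars cover 39 pixels, oblique ones
~43); intensities are uniform in [0.8, 1.0] and per-pixel rates are
normalised so each image emits ~1000 spikes/s in total. Frequency sweeps
activate one channel per `inter_channel_dt` (forward, backward, or
forked from the middle channel outward).

These are caricatures: real retinal/cochlear spike trains have temporal
structure, adaptation and correlations that Poisson thinning does not
produce. A green experiment-level test establishes that the *rule plus
schedule* produce the classical effect under these idealised drives, not
that they would on natural input.

## 6. The experiments and their calibration

None of the classical protocols reproduced here prints its neuron or
rule constants, so each fixture fixes them once, with the reasoning
below; the structural parameters (population sizes, rates, durations,
the −9 nA lateral inhibition, 128 ms / 2 ms windows) are as stated in
the protocols.

**Burst and sequential fixtures (3→2 and 10→2).** The initial weight is
the closed-form calibration ("n spikes just reach threshold",
margin 1.001) and the bounds are fixed multiples of it (1.6 and 5.5).
For "fires after two spikes" to be observable, the two-spike response
must cross threshold *before the third input arrives* — 2 ms later. With
the generic 20/5 ms time constants a single EPSP peaks ~9 ms after
arrival, so that geometry is impossible; the fixtures use fast membranes
(\(\tau_m = 10\) ms, \(\tau_{syn} = 1\)–2 ms), under which the
calibrated ratios work out with double-digit margins
(burst: \(1.6\,\mathrm{peak}_2 > \mathrm{peak}_3\) but
\(1.6\,\mathrm{peak}_1 < \mathrm{peak}_3\); sequential:
\(5.5\,\mathrm{peak}_1 < \mathrm{peak}_{10}\)).
`spikes_to_fire()` counts input spikes whose *arrival* is at or before
the first postsynaptic spike — the causal count.

**Synaptic competition (1000 inputs, 300 s).** Classical amplitudes
(\(A_+ = 0.005\,w_{max}\), \(A_-/A_+ = 1.05\), τ = 20 ms). The free
choice is \(w_{max}\): competition requires individually meaningful
synapses, so \(w_{max} = 4\) nA (single EPSP ≈ 0.6 mV). The output rate
then self-regulates from ~200 Hz to ~22 Hz while ~90% of weights land
within 10% of a bound. Honest caveat: the strong group stabilises in the
upper interior rather than exactly at \(w_{max}\) — the bimodality
metric is carried by the weak group plus the spread, and the "strong"
synapses are the upper tail that holds the neuron's drive.

**Orientation selectivity.** The mechanism as specified — mean-rate
sliding threshold plus static, weak lateral inhibition — has two stable
defect states that simple parameter choices hit almost surely: *twin
units* locked onto the same orientation (both respond above their own
mean, so neither depresses; breaking the tie needs an inhibitory loop
gain above one), and *dead units* (a silenced neuron has
\(r_{post} = 0\), hence \(\Delta w = -\epsilon w\) only, and never
re-enters). The fixture therefore (i) draws initial weights from a wide
range so receptive fields start heterogeneous, (ii) operates the outputs
in the linear part of the rate-current curve (peak responses ~50–70 Hz,
far from the refractory ceiling, where response *contrast* survives),
(iii) equilibrates θ via `theta0`, and (iv) gives each output an
independent 300 Hz background-noise input — spontaneous drive that keeps
suppressed units weakly active and plastic. With these, all five tested
seeds end with the four outputs preferring the four training
orientations (one each), and removing lateral inhibition reproduces the
classical negative control (no selectivity split). Preferred angles are
read from tuning curves at 10° steps and assigned to the nearest
training orientation (circular distance, period 180°).

**Voltage-gated demonstrations.** The potentiation protocol holds the
membrane above \(\theta_V\) with a bias current during pairing; the
depression protocol runs without bias so arrivals see a membrane at or
below the gate. Each protocol zeroes the opposite jump (a demo of one
branch at a time); calcium eligibility comes from the neuron's own
responses to previous presentations (τ_C = 150 ms at a 200 ms period).

**Temporal-pattern learning.** 16 channels, delays
\(|j-k|\cdot 10 + 2\) ms on the cross-channel plastic feedback. At 1 ms
resolution with one-spike-per-channel drive, the postsynaptic membrane
around a feedback arrival is dominated by the neuron's own reset, so the
membrane bit is uninformative exactly where the coincidence lives; the
fixture holds the gate open (\(\theta_V\) below reset) and lets the
calcium window (τ_C = 15 ms) do the coincidence detection: feedback
arriving within a few ms after the channel's own spike potentiates,
feedback one channel-lag late (≥ 22 ms) falls outside the interval, and
everything unpotentiated drifts to \(w_{min}\) through the bistable
down-branch. The membrane gate itself is exercised both ways by the
demonstration protocols above. The learned matrix is summarised by
\((\sum_{j<k} w_{jk} - \sum_{j>k} w_{jk})/\sum w\): positive for forward
sweeps, negative for backward, ≈0 (|·| < 0.1 observed) for forked —
the forked value is not exactly zero because an even channel count makes
the "middle" channel off-centre by half a channel.

## 7. Numerical conventions and degenerate inputs

- Exact exponential propagators everywhere (membrane, synaptic current,
  traces, calcium); the trace semigroup property is tested.
- Bin centres represent spike times inside windows; windows are
  half-open; a boundary spike belongs to the new window.
- \(\Delta t = 0\) pairs depress (\(F(0) = -A_-\)); the drift boundary
  \(w = \theta_W\) uses the downward branch; clipping happens once per
  pass after accumulation.
- Duration 0 returns empty recordings; empty rows, empty windows and
  silent projections are all well-defined no-ops (except relaxation
  terms, which act regardless).
- Non-finite neuron state aborts the simulation naming the neuron and
  millisecond. Delays longer than the ring buffer are a build-time
  configuration error.
- One master seed feeds named sub-streams (connectivity, weights,
  delays, each stimulus population), so components can be varied
  independently; identical (network, duration, seed) reproduce
  bit-identical recordings.

## 8. Known limitations

- The plasticity pass is serialised with the neural loop; concurrency
  effects of a real two-core implementation (memory contention, pass
  overrun) are not modelled, and neither is fixed-point weight
  arithmetic.
- Current-based synapses with a single shared \(\tau_{syn}\) per neuron;
  no conductances, no sub-millisecond events.
- The per-pre-spike (DED) alternative is implemented as accounting only,
  not as a second full plasticity engine.
- Experiment-level conclusions hold for the calibrated fixtures; the
  orientation experiment in particular documents that the bare mechanism
  without heterogeneity, linear-regime operation and background noise
  regularly falls into twin/dead defect states.
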