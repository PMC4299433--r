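# plastisim

Simulation of spiking neural networks in which synaptic plasticity is
computed in **batched passes over the weight matrix** rather than
synapse-by-synapse at every spike. The neural side runs at a 1 ms
resolution (current-based leaky integrate-and-fire neurons, integer
synaptic delays reintroduced at the postsynaptic end through per-neuron
ring buffers); spikes are condensed into double-buffered **spike-history
bitmaps** (2 ms bins over a 128 ms window), and once per window a
plasticity pass walks every synaptic row once, applies the configured
learning rule to the completed window, and writes each row back exactly
once. For a row whose presynaptic neuron fires at 24 Hz this costs 8
write-backs per second instead of the 24 a per-pre-spike
(deferred-event-driven) scheme would pay — the batching argument the
package makes measurable through its write-back ledger.

The package is for computational neuroscientists who want to study how
this batched schedule interacts with learning rules of very different
character. Three rules operate on the windowed history:

- **Trace-based STDP** (all-to-all pairing). Pair weight changes follow
  the double-exponential kernel
  `F(Δt) = A₊ exp(Δt/τ₊)` for `Δt < 0` and `−A₋ exp(−Δt/τ₋)` for
  `Δt ≥ 0`, with `Δt = (t_pre + d) − t_post` — the synaptic delay `d` is
  applied *before* comparison. Instead of enumerating pairs, each synapse
  carries an exponentially decaying trace of presynaptic arrivals and
  each neuron a trace of its spikes; the batched update equals the
  explicit all-pairs sum to floating-point accuracy (a tested property),
  including for delays that push arrivals across window boundaries.
- **BCM** (rate-based): `dw/dt = [r_post (r_post − θ) r_pre] δ − ε w`,
  with the modification threshold θ sliding as an exponential moving
  average of the postsynaptic window rate, so activity above the
  neuron's own mean potentiates and activity below it depresses.
- **Voltage-gated bistable STDP**: at each presynaptic arrival the weight
  jumps `+a` if the postsynaptic membrane exceeds θ_V and a calcium trace
  `C(t)` (incremented by `J_C` per postsynaptic spike, decaying with
  τ_C) lies in the potentiation interval `[θ^h_down, θ^h_up)`, jumps `−b`
  under the mirror condition, and otherwise drifts toward one of two
  stable states (`w_max` above θ_W at rate α, `w_min` below at rate β).

Classical learning experiments are scripted as fixtures: latency
reduction of the response to a repeated pattern, teacher-driven
potentiation (STDP and BCM), the splitting of 1000 uncorrelated inputs
into weak and strong synapse groups, the emergence of orientation
selectivity under BCM with lateral inhibition, voltage-gated
potentiation/depression protocols, and temporal-pattern learning through
delay-line coincidence detection with tonotopic frequency sweeps.

## Worked example

A single input fires a 3-spike burst (2 ms apart) every 50 ms through one
plastic synapse. The initial weight `w0` is calibrated from the
closed-form LIF response so that exactly three spikes reach threshold;
the bound is `1.6 w0`; depression is off.

```r
library(plastisim)
b <- run_burst_experiment(seed = 1)
b$metrics$spikes_to_fire
#>  [1] 3 3 3 2 2 2 2 2 2 2 2 2
round(c(w0 = b$metrics$w0, w_final = b$metrics$w_final), 2)
#>      w0 w_final
#>   71.81  114.90
```

At the first presentations three input spikes are needed to make the
neuron fire; within 400 ms potentiation saturates the weight at the bound
(`114.9 = 1.6 × 71.8` nA) and the neuron fires after only two spikes.

The write-back ledger of any plastic run compares the batched schedule
with per-pre-spike (DED) accounting; with a 24 Hz presynaptic neuron
simulated for 1000 ms:

```r
rec <- run_network(net, duration_ms = 1000, seed = 1)  # net: one plastic row
count_writebacks(rec$ledgers[[1]], "batched")  # 8
count_writebacks(rec$ledgers[[1]], "ded")      # 24
```

The synaptic-competition experiment (1000 Poisson inputs at 20 Hz onto
one neuron, 300 s) ends with 90.6% of the weights within 10% of a bound
(`run_song_experiment(seed = 1)$metrics$bimodality_final` is 0.906,
starting from 0), and the orientation experiment assigns each of the four
output neurons a distinct preferred bar orientation on all five tested
seeds (`run_orientation_experiment(seed = 1)$metrics$assigned_deg` is
`0 90 45 135`) — and fails to do so when lateral inhibition is removed.

## Command line

```sh
Rscript -e 'plastisim::plastisim_main()' validate --config inst/extdata/configs/poisson_stdp.json
Rscript -e 'plastisim::plastisim_main()' simulate --config inst/extdata/configs/poisson_stdp.json --out out/
Rscript -e 'plastisim::plastisim_main()' run-experiment song --seed 1 --out out/
```

(the same entry point is installed as `inst/cli/plastisim`). Experiment
names: `latency`, `burst_stdp`, `teacher_stdp`, `song`, `bcm_teacher`,
`orientation`, `vg_demo`, `temporal`. Outputs are plain text: a spike
raster (`spikes.csv`), membrane traces, per-boundary weight-matrix
snapshots, the write-back ledger, `metrics.json` and a reproducibility
manifest.

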