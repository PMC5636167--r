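---
title: "Model and methods: reward-modulated STDP in a spiking foraging network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: reward-modulated STDP in a spiking foraging network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`stdpforage` simulates a virtual agent whose "brain" is a three-layer
feed-forward network of spiking map neurons, learning a foraging task from
reward alone: no labels, no gradients, only spike-timing-dependent plasticity
(STDP), a delayed global reward signal, and a battery of homeostatic
mechanisms that keep the learning stable. This vignette describes the model,
the constants it runs on, the decisions we had to make where the design was
genuinely open, and what the test suite does and does not establish.

## The agent and its world

The environment is a 50 x 50 toroidal grid. In the *single-food* task, 10%
of cells (250) hold one food particle each; a consumed particle respawns at a
random empty cell, so the density is stationary. In the *pattern* task, food
comes in two-cell pairs -- horizontal pairs are rewarded, vertical pairs are
"toxic" -- with rewarded-particle density one quarter of the single task
(31 horizontal plus 31 vertical pairs) and no two patterns adjacent in the
8-neighborhood, so every pattern is unambiguous. Landing on either cell of a
pair removes both and respawns a fresh pair of the same orientation.

The agent sees a 7 x 7 window centered on itself (the center cell is always
empty: food there would already have been eaten) and moves one cell per
movement cycle in one of 8 directions. We made the grid toroidal because the
benchmark statistics we target (acquisition rates at fixed density) assume
stationary food statistics; reflecting or absorbing boundaries would make
them position-dependent.

## Neurons

Each of the 842 cells (49 input, 784 hidden, 9 output) is a two-dimensional
map of a fast-spiking neuron iterated at 0.5 ms per step:

$$v_{n+1} = f_\alpha(v_n, v_{n-1}, i_n + \beta^e i^{ext}_n), \qquad
  i_{n+1} = i_n - \mu (v_{n+1} + 1) + \mu\sigma + \mu\sigma^e i^{ext}_n$$

with the piecewise fast map `f_alpha()` (subthreshold branch
$\alpha/(1-v) - 1 + i$, a one-step spike peak at $\alpha + i$, then a reset
to $-1$), $\alpha = 3.65$, $\mu = 5\times10^{-4}$, $\sigma = 0.06$,
$\beta^e = 0.133$, $\sigma^e = 1$. The slow-variable update is written with
$(v + 1)$ inside the parenthesis; this is the form under which the map has a
silent fixed point at $v^* = \sigma - 1 = -0.94$ (about $-62$ mV under the
affine conversion $v_{ph} = 50v - 15$ mV). Note how close the resting point
sits to the saddle-node at $\sigma \approx 0.0604$: these neurons are
deliberately hair-triggered, and a sustained input current of only a few
times $10^{-4}$ destabilizes rest. All neurons are initialized at the
numerically settled fixed point so trials start from silence.

A "spike" is registered on the step the peak branch fires -- one spike per
peak, always followed by a reset step. Input cells holding food in the
visual field receive `i_ext = 1` for 2 steps at each epoch start, which
reliably evokes exactly one spike (a property the test suite asserts).

## Synapses and inhibition

Conductances follow a one-step kinetic scheme: decay by `gamma = 0.9` per
step (about 5 ms) and jump on each presynaptic spike by
$(1 + XR)\,\kappa\, w / W^{ref}$, with $X \sim U(-1,1)$ drawn independently
per release and $R = 0.12$ the release-noise amplitude that the noise sweeps
vary. Currents are $-g (v - v_{rp})$ with reversal potentials $0$
(excitatory, $-15$ mV) and $-1.1$ (inhibitory, $-70$ mV).

Two normalization choices deserve explanation:

* **Reference sum.** The increment divides by $W^{ref}_j$, the postsynaptic
  cell's *initial* target input sum. Dividing by the *running* homeostatic
  target (available as `conductance_norm = "current"`) would cancel
  homeostatic gain control exactly -- heterosynaptic rescaling keeps
  $\sum_i w_{ij} = W_{j0}$, so $w/W_{j0}$ never changes when $W_{j0}$ does --
  and the homeostatic mechanism would be decorative. With a fixed reference,
  raising a cell's target scales up its synaptic efficacy, which is what
  homeostatic scaling means.
* **Layer gains.** The absolute excitability of a layer is not pinned by the
  model equations (only relative weights are). The gains
  `kappa_hidden = 0.27` and `kappa_output = 5` were calibrated once, at
  design time, so that the untrained network responds to typical stimuli in
  a usable regime: a hidden cell needs roughly three coincident average
  inputs to fire (no single input suffices), and the output layer produces a
  few first-half spikes per epoch. They are configuration constants, not
  fitting knobs.

Feed-forward inhibition is *virtual*: each cell projects an inhibitory
connection to exactly the cells it excites, with the uniform weight equal to
the mean of its excitatory output weights, recomputed whenever excitatory
weights change. Total inhibition therefore always equals total excitation
per cell. No interneurons are modeled and inhibition arrives with no extra
delay by default (`inh_delay_ms` exists for experimentation; in our hands a
2-10 ms disynaptic lag either did nothing or silenced the hidden layer,
because map-neuron spike latencies near threshold are tens of milliseconds).

## Plasticity

Four interacting rules operate on the excitatory weights.

**STDP traces.** A pre/post spike pair within 120 ms (3 time constants)
creates a trace $tr = \pm K e^{-|\Delta t| / T_c}$, $K = 0.04$, $T_c = 40$
ms; potentiating when the postsynaptic spike does not precede the
presynaptic one. Pairing is all-to-all within the window, including across
epoch boundaries.

**Non-rewarded STDP (input to hidden).** Each pairing acts immediately: the
trace value is added to the weight, the weight is clipped to $[0, w_{max}]$,
and the cell's other inputs are rescaled so its input sum is unchanged
(heterosynaptic balancing). Because every input spike happens at epoch start
and affects conductances before any weight change could matter, applying the
epoch's events in order at its end is exactly equivalent to
applying them "immediately", and that is how the implementation batches them.

**Rewarded STDP (hidden to output).** Pairings are stored as eligibility
traces with epoch-resolution timestamps, live for 6 epochs, and are
converted to weight changes whenever the reward signal arrives (every epoch:
food gives $s_{rp} = +1$, toxic food $-0.5$, foodless moves $-0.1$ in the
single task and $-0.01$ in the pattern task):

$$W_{ij} \leftarrow W_{ij} \prod_k \left(1 + \frac{W_{i0}}{W_i}\,
  s_{rp}\, \frac{tr_k}{t - t_k + 1}\, \frac{|Sum_{tr}|}{Avg_{tr}}\right)$$

The $W_{i0}/W_i$ factor (output balancing) damps growth of hidden cells
whose total output already grew; the $|Sum_{tr}|/Avg_{tr}$ factor (trace
normalization) damps synapses whose trace history is chronically strong,
where $Avg_{tr}$ is a per-synapse EMA (rate 0.001) of the magnitude of the
recency-weighted trace sum. The EMA starts at the first nonzero sum a
synapse produces; before that the ratio is clamped to 1.

Three numerical guards keep the multiplicative scheme sane over $10^4$-epoch
runs, and were added after observing exactly the failure they prevent
(weights collapsing to zero and a divide-by-zero in the subsequent
rescaling): the normalization ratio is bounded by 20, each per-trace factor
is clipped to $[0.5, 2]$, and $Avg_{tr}$ is floored at
$\delta K = 4 \times 10^{-5}$ (the asymptotic average of a synapse tagged
about once per EMA memory). Rarely-tagged synapses still learn much faster
than chronically tagged ones -- the stated purpose of the mechanism -- but
boundedly so.

**Homeostatic scaling.** Per cell, an EMA (rate 0.005/epoch) of the
per-epoch spike count is compared with the target rate (hidden 0.4 Hz,
output 5/3 Hz -- the repeating decimal "1.6..." read as 5/3, exactly 0.5
spikes per 300 ms epoch); the target input sum is multiplied by
$1 \pm 10^{-4}$ each epoch accordingly, and heterosynaptic rescaling then
enforces the new target exactly. Targets are bounded above by 90% of
`fan_in` times the weight cap: beyond that bound the target is not
achievable without every synapse pinned at the cap, and the rescale/clip
pair would fight forever.

**Hard caps.** The weight cap is expressed in multiples of the
single-input spike threshold, which is measured by bisection at build time
(`spike_threshold()`). For the pattern task the input-side factor is 0.6:
no single input may fire a hidden cell, which is precisely what forces
hidden cells to become two-particle pattern detectors. For the single-food
task the factor is 1.5: a mature synapse may relay an isolated food
position on its own. We found the subthreshold cap incompatible with the
single-food task -- with it, the hidden code is purely combinatorial
(coincidence-only), and even a supervised linear readout of hidden spike
counts forages at only ~25%, far below the level the foraging task demands;
with relay-capable synapses, non-rewarded STDP bootstraps position-selective
hidden cells (first coincidences potentiate a cell's co-active inputs, then
single strengthened inputs suffice).

## The decision loop

Each epoch: stimulate, integrate 600 steps, count output spikes over the
first 300 steps, pick the direction whose (non-center) output cell spiked
most -- ties broken uniformly, silence keeps the previous heading -- then
move, classify the outcome, apply the reward to the stored traces, and run
the homeostatic housekeeping. A random-move override (floor 1%) escapes
movement loops; its probability grows by 0.5% (single task, reset on food)
or 1% (pattern task, no reset) per foodless move.

The acquisition rate is tracked as an EMA over moves with constant 0.002
(about a 500-move memory); discrimination accuracy is the good-food share of
all food over a trailing 2000-move window.

## Heuristic baselines

Four reference agents: the 98%-straight/2%-turn random walk; adjacent-grab;
nearest-food (Chebyshev distance, as befits 8-directional moves); and the
exhaustive 5-move lookahead, which enumerates all $8^5$ move sequences
confined to the visual field (food consumed in a rollout is not re-counted),
prefers more food, then earlier acquisition, then uniform random among the
optimal first moves. The lookahead reproduces the ~56% benchmark rate at
10% density and anchors the upper reference line; the ordering
random walk < adjacent-grab < nearest-food < lookahead is asserted in the
tests.

## What the synthetic environment does and does not capture

The generator reproduces the study conditions exactly: densities, pair
geometry and non-adjacency, respawn-on-consumption stationarity, the 7 x 7
aperture. It does not model anything a real foraging environment would add
-- occlusion, sensory noise, variable food value, non-stationary density --
so passing tests demonstrate the learning machinery under the stated ideal
conditions only.

## Problem sizes and determinism

The test suite runs the full 842-neuron network but keeps training runs to a
few thousand epochs, the scale at which the qualitative effects (mechanism
ablation orderings, noise dependence, inhibition-variance effects) are
already measurable; the acceptance script trains full runs of 2 x 10^4
epochs, the horizon at which the learning-curve statistics are quoted. All
randomness flows from a single integer seed: R's RNG drives building,
environments and decisions, and hands a fresh sub-seed to the compiled epoch
kernel (a Mersenne Twister local to the call), so end-to-end runs are exactly
reproducible and independent of the platform's C++ library.

## Known limitations

* Absolute excitability (the layer gains), the inhibitory reversal, and the
  conductance decay are not derivable from the model equations; they are
  design-time calibrations and other choices plausibly change quantitative
  outcomes.
* The movement decision reads an argmax over first-half output spike
  counts. Those counts are small integers from a population whose cells all
  receive the same feed-forward stream (uniform initial weights, all-to-all
  wiring, mirrored inhibition), differing only through per-release noise;
  they therefore tie, or all stay silent, on the large majority of epochs,
  across every operating point we examined (conductance decay, inhibitory
  reversal, layer gains, target rates). Under the default calibration the
  reward-driven differentiation this readout would need does not build up,
  and trained acquisition rates remain near the random-movement baseline
  rather than approaching the lookahead benchmark -- the acceptance script
  reports whatever the full training horizon actually achieves. The
  rule-level properties of every plasticity mechanism (trace algebra,
  balancing, normalization, homeostasis) are exact and unit-tested
  independently of this system-level limitation.
* Negative and positive traces share one normalizer (appropriate for this
  feed-forward architecture; a model with feedback loops would need them
  separated).
* The pattern task disables input-side inhibition by default (as the
  pattern-classification analysis requires reliable pair responses); setting
  `inhibition_in = TRUE` there is possible but untested territory.
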