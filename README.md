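# stdpforage

Spiking neural networks that learn a foraging task through reward-modulated
spike-timing-dependent plasticity (STDP).

A virtual agent lives on a 50 x 50 grid scattered with food. Its brain is a
feed-forward network of 842 map-based (Rulkov) spiking neurons — a 7 x 7
input layer driven by the agent's visual field, a 28 x 28 hidden layer, and a
3 x 3 output layer whose most active cell picks the next movement direction.
The input projection learns by classical (non-rewarded) STDP; the output
projection stores STDP pairings as eligibility traces ("synaptic tags") and
converts them to weight changes only when a global reward or punishment
signal arrives:

    W_ij <- W_ij * prod_k [ 1 + (W_i0 / W_i) * s_rp * tr_k / (t - t_k + c)
                                * |Sum_tr| / Avg_tr ],
    tr_k = ±K exp(-|Δt| / T_c)

with reward `s_rp = +1` for food, `-0.5` for toxic food, and a small
punishment on foodless moves. Learning is kept stable by heterosynaptic
rescaling (each cell's summed input is conserved), homeostatic scaling of
per-cell input targets toward target firing rates, output-sum balancing
(`W_i0 / W_i`), normalization of updates by each synapse's trace history
(`Sum_tr / Avg_tr`), hard weight caps anchored to the measured single-input
spike threshold, mirrored feed-forward inhibition, and multiplicative
synaptic release noise (`R = 0.12`) that drives trial-and-error exploration.

The package is aimed at computational neuroscientists who want to run, probe
and ablate this model class: every mechanism is an independent switch in
`network_config()`, the two tasks (single food particles vs. rewarded
horizontal / punished vertical food pairs) are built in, and four heuristic
reference agents (random walk, adjacent-grab, nearest-food, exhaustive
5-move lookahead) provide the benchmark lines.

## A worked example

```r
library(stdpforage)

# the exhaustive 5-move-lookahead reference agent at 10% food density
h <- run_heuristic("exhaustive5", n_moves = 10000, seed = 1)
h$rate
#> [1] 0.5792
```

About 56–58% of this agent's moves acquire food — the practical ceiling for
a bounded-lookahead forager at this density, against which the spiking model
is judged.

```r
# a (short) training run of the full model on the single-food task
run <- train(network_config(), n_epochs = 2000, seed = 1, task = "single")
run
#> <forage_run> single task, 2000 epochs
#>   final acquisition EMA: 4.2%
measure_ties_and_zeros(run) # decision diagnostics (tie / silent epochs)
#>  ties zeros
#>  1057   640
```

The diagnostics are the interesting part: over 80% of the epochs end in a
tied or silent output layer, so most moves carry no direction signal from
the network — the system-level limitation discussed at the end of the
methods vignette. The learning-curve statistics belong to the 20 000-epoch
horizon used by the acceptance script. Mechanism ablations are plain
configuration switches:

```r
train(network_config(heterosynaptic = FALSE), n_epochs = 2000, seed = 1)
train(network_config(synapse = synapse_params(release_cv = 0.001)),
      n_epochs = 2000, seed = 1)  # low release noise
```

and the plasticity algebra is exposed directly (`stdp_trace_value()`,
`collect_pairings()`, `apply_reward()`, `heterosynaptic_rescale()`,
`homeostatic_update()`, ...) for unit-level experiments. See the methods
vignette (`vignettes/methods.Rmd`) for the model description and the
reasoning behind every constant.

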