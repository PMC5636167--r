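Package: stdpforage
Title: Reward-Modulated STDP Spiking Networks Learning a Foraging Task
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a three-layer feed-forward network of map-based
    (Rulkov) spiking neurons that learns a grid-world foraging task through a
    combination of non-rewarded spike-timing-dependent plasticity (STDP) in
    the input-to-hidden projection and reward-modulated STDP with eligibility
    traces in the hidden-to-output projection. Implements the homeostatic
    machinery the learning depends on (heterosynaptic input rescaling,
    homeostatic target-rate scaling, output-sum balancing, trace-history
    normalization, mirrored feed-forward inhibition, multiplicative synaptic
    release noise), the virtual foraging environments (random single food
    particles and horizontal/vertical food-pair patterns), the decision-making
    agent, and heuristic baseline agents for performance reference.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
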