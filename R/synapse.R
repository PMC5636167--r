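#' Parameters of the kinetic synapse
#'
#' Synaptic conductance follows a first-order kinetic scheme in discrete time:
#' it relaxes geometrically with factor `gamma` per step and jumps on each
#' presynaptic spike by an amount drawn from a flat distribution
#' `(1 + X * release_cv)` times the synaptic strength, `X ~ U(-1, 1)`. The
#' reversal potential distinguishes excitatory from inhibitory synapses.
#'
#' @param gamma Conductance relaxation factor per 0.5 ms step, `0 <= gamma < 1`
#'   (default 0.9, about a 5 ms decay constant).
#' @param release_cv Coefficient of variability of synaptic release `R`
#'   (default 0.12).
#' @param v_rp_exc Excitatory reversal potential, dimensionless (default 0,
#'   i.e. -15 mV).
#' @param v_rp_inh Inhibitory reversal potential, dimensionless (default -1.1,
#'   i.e. -70 mV).
#' @param inh_delay_ms Lag of feed-forward inhibition behind excitation in ms
#'   (default 0: simultaneous with excitation). Inhibition is disynaptic (it stands in for a population of
#'   unmodeled interneurons), so it arrives a small synaptic delay after the
#'   monosynaptic excitation; the transient excitation-only window lets the
#'   most strongly driven cells of a layer spike before the volley-scaled
#'   inhibition clamps the rest.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(gamma = 0.9, release_cv = 0.12,
                           v_rp_exc = 0, v_rp_inh = -1.1,
                           inh_delay_ms = 0) {
  stopifnot(gamma >= 0, gamma < 1, release_cv >= 0, inh_delay_ms >= 0)
  structure(list(gamma = gamma, release_cv = release_cv,
                 v_rp_exc = v_rp_exc, v_rp_inh = v_rp_inh,
                 inh_delay_ms = inh_delay_ms),
            class = "synapse_params")
}

#' One update of a synaptic conductance
#'
#' `g' = gamma * g` plus, if the presynaptic cell spiked this step,
#' `(1 + x * R) * g_strength / w_target_post`. The division normalizes the
#' increment by the postsynaptic cell's reference input strength so that only
#' relative synaptic weights set the drive.
#'
#' @param g Current conductance (>= 0).
#' @param g_strength Synaptic strength (weight) of this connection.
#' @param w_target_post Reference input strength of the postsynaptic cell
#'   (> 0); defaults to 1 (already-normalized weights).
#' @param pre_spiked Did the presynaptic cell spike this step?
#' @param x Release-noise draw in [-1, 1] (0 for a deterministic synapse).
#' @param params A [synapse_params()] object.
#' @return The updated conductance.
#' @export
conductance_step <- function(g, g_strength, w_target_post = 1,
                             pre_spiked = FALSE, x = 0,
                             params = synapse_params()) {
  if (w_target_post <= 0) stop("w_target_post must be positive")
  out <- params$gamma * g
  if (pre_spiked) {
    out <- out + (1 + x * params$release_cv) * g_strength / w_target_post
  }
  out
}

#' Synaptic current from a conductance
#'
#' `i_syn = -g * (v_post - v_rp)`: depolarizing for an excitatory synapse
#' whenever the postsynaptic membrane sits below the reversal potential.
#'
#' @param g Conductance (>= 0).
#' @param v_post Postsynaptic membrane variable (dimensionless).
#' @param v_rp Reversal potential (dimensionless).
#' @return The synaptic current.
#' @export
synaptic_current <- function(g, v_post, v_rp) -g * (v_post - v_rp)

#' Mirrored feed-forward inhibition weight of a cell
#'
#' Inhibition is not carried by explicit interneurons: each cell projects a
#' virtual inhibitory connection to every cell it excites, with a uniform
#' weight equal to the mean of its excitatory output weights. The total
#' inhibitory output of a cell therefore always equals its total excitatory
#' output, and the mirror must be recomputed whenever excitatory weights
#' change.
#'
#' @param weights Numeric vector of the cell's excitatory output weights
#'   (non-empty).
#' @return The uniform inhibitory weight (mean of `weights`).
#' @export
mirror_inhibition <- function(weights) {
  if (length(weights) == 0) stop("cell has no excitatory outputs")
  mean(weights)
}

#' Single-pulse spike threshold of a neuron driven by one kinetic synapse
#'
#' Measures, by bisection, the smallest instantaneous excitatory conductance
#' (delivered once to a resting neuron and decaying with `gamma`) that evokes
#' a spike within `max_steps` steps. This empirical threshold anchors the hard
#' upper limit on synaptic strength: the cap is set below it so that no single
#' synaptic input can fire a cell.
#'
#' @param np A [neuron_params()] object.
#' @param sp A [synapse_params()] object.
#' @param max_steps Observation horizon in steps (default 600, one epoch).
#' @param tol Bisection tolerance (default 1e-6).
#' @return The threshold conductance.
#' @export
spike_threshold <- function(np = neuron_params(), sp = synapse_params(),
                            max_steps = 600, tol = 1e-6) {
  rest <- rulkov_rest(np)
  fires <- function(g0) {
    st <- rest
    g <- g0
    for (k in seq_len(max_steps)) {
      st <- rulkov_step(st, np, synaptic_current(g, st$v, sp$v_rp_exc))
      if (st$spiked) return(TRUE)
      g <- sp$gamma * g
    }
    FALSE
  }
  lo <- 0
  hi <- 0.05
  while (!fires(hi)) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}
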