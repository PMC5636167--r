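#' Parameters of the map-based fast-spiking neuron
#'
#' The model neuron is a two-dimensional discrete-time map (a Rulkov map) with
#' a fast membrane variable `v` and a slow adaptation variable `i_slow`. One
#' map iteration corresponds to one simulation step of 0.5 ms, so a 600-step
#' epoch is roughly 300 ms.
#'
#' @param alpha Nonlinearity parameter of the fast map (default 3.65).
#' @param mu Update rate of the slow variable; `mu << 1` (default 0.0005).
#' @param sigma Baseline excitation of the slow variable (default 0.06). At
#'   rest the membrane variable settles at `v = sigma - 1`.
#' @param beta_e Coupling of external/synaptic current into the fast variable
#'   (default 0.133).
#' @param sigma_e Coupling of external/synaptic current into the slow variable
#'   (default 1).
#' @return An object of class `neuron_params`.
#' @examples
#' p <- neuron_params()
#' v_to_mv(rulkov_rest(p)$v) # resting potential in mV
#' @export
neuron_params <- function(alpha = 3.65, mu = 5e-4, sigma = 0.06,
                          beta_e = 0.133, sigma_e = 1) {
  stopifnot(alpha > 0, mu > 0, mu < 1)
  structure(list(alpha = alpha, mu = mu, sigma = sigma,
                 beta_e = beta_e, sigma_e = sigma_e),
            class = "neuron_params")
}

#' Piecewise fast map of the spiking neuron
#'
#' Three branches: a subthreshold branch for `v <= 0`, a spike-peak branch
#' returning `alpha + i`, and a reset branch returning -1. The peak branch
#' requires the previous value of `v` to be non-positive, which makes the map
#' emit exactly one peak per spike before resetting.
#'
#' @param v Current fast variable.
#' @param v_prev Fast variable at the previous step (the branch condition is
#'   second order).
#' @param i Total slow + input drive entering the fast map.
#' @param params A [neuron_params()] object.
#' @return The next value of the fast variable.
#' @export
f_alpha <- function(v, v_prev, i, params = neuron_params()) {
  a <- params$alpha
  if (v <= 0) {
    if (v == 1) stop("invalid neuron state: v = 1 on the subthreshold branch")
    a / (1 - v) - 1 + i
  } else if (v < a + i && v_prev <= 0) {
    a + i
  } else {
    -1
  }
}

#' Advance the map neuron one step
#'
#' Updates the fast variable through [f_alpha()] and the slow variable through
#' `i_{n+1} = i_n - mu * (v_{n+1} + 1) + mu * sigma + mu * sigma_e * i_ext`.
#' External drive enters the fast map as `beta_e * i_ext`. A spike is
#' registered on the step in which the peak branch is taken.
#'
#' @param state A list with `v`, `v_prev`, `i_slow` (see [rulkov_rest()]).
#' @param params A [neuron_params()] object.
#' @param i_ext External (synaptic plus stimulation) current for this step.
#' @return The updated state list; `state$spiked` is `TRUE` on peak steps.
#' @export
rulkov_step <- function(state, params = neuron_params(), i_ext = 0) {
  a <- params$alpha
  drive <- state$i_slow + params$beta_e * i_ext
  spiked <- state$v > 0 && state$v < a + drive && state$v_prev <= 0
  v_new <- f_alpha(state$v, state$v_prev, drive, params)
  # grouped to match the compiled kernel's floating-point association exactly
  i_new <- state$i_slow + (-params$mu * (v_new + 1) +
    params$mu * params$sigma + params$mu * params$sigma_e * i_ext)
  list(v = v_new, v_prev = state$v, i_slow = i_new, spiked = spiked)
}

#' Iterate the map neuron over many steps (reference implementation)
#'
#' Plain-R trajectory of a single neuron, used for unit testing and for
#' cross-checking the compiled network kernel.
#'
#' @param n Number of steps.
#' @param params A [neuron_params()] object.
#' @param i_ext External current: a scalar or a length-`n` vector.
#' @param state Initial state; defaults to the resting state.
#' @return A list with the `v` trajectory, the final `state`, and the integer
#'   vector `spike_steps` (1-based step indices of spike peaks).
#' @export
rulkov_run <- function(n, params = neuron_params(), i_ext = 0,
                       state = rulkov_rest(params)) {
  ie <- rep_len(i_ext, n)
  v <- numeric(n)
  spikes <- integer(0)
  for (k in seq_len(n)) {
    state <- rulkov_step(state, params, ie[k])
    v[k] <- state$v
    if (state$spiked) spikes <- c(spikes, k)
  }
  list(v = v, state = state, spike_steps = spikes)
}

#' Resting state of the map neuron
#'
#' The model is initialized at its silent fixed point so that trials start
#' from rest. The fixed point is found numerically by iterating the map
#' without input; for the default parameters it converges to
#' `v = sigma - 1 = -0.94`.
#'
#' @param params A [neuron_params()] object.
#' @param n_settle Number of settling iterations (default 20000).
#' @return A state list with components `v`, `v_prev`, `i_slow`, `spiked`.
#' @export
rulkov_rest <- function(params = neuron_params(), n_settle = 20000) {
  state <- list(v = params$sigma - 1, v_prev = params$sigma - 1,
                i_slow = 0, spiked = FALSE)
  for (k in seq_len(n_settle)) state <- rulkov_step(state, params, 0)
  state$spiked <- FALSE
  state
}

#' Convert the dimensionless membrane variable to millivolts
#'
#' `v_ph = 50 v - 15` mV; the resting value `v = -0.94` maps to -62 mV.
#'
#' @param v Dimensionless membrane variable (any numeric vector).
#' @return Membrane potential in mV.
#' @export
v_to_mv <- function(v) 50 * v - 15

#' Inverse of [v_to_mv()]
#' @param mv Membrane potential in mV.
#' @return Dimensionless membrane variable.
#' @export
mv_to_v <- function(mv) (mv + 15) / 50
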