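#' Parameters of the plasticity and homeostasis rules
#'
#' Bundles the constants of the four interacting rules: the STDP trace
#' (amplitude `K`, time constant `T_c`, pairing window), reward-gated trace
#' application (recency constant `c`, trace lifetime, EMA rate `delta` of the
#' per-synapse trace-history average), homeostatic target scaling (`d_tar`,
#' firing-rate EMA rate), and the immediate non-rewarded STDP of the input
#' projection.
#'
#' @param K STDP amplitude at zero lag (0.04; sign set by pairing order).
#' @param T_c STDP time constant in ms (40).
#' @param pairing_window Maximum |t_post - t_pre| in ms for a pairing to
#'   create a trace (default 120 ms = 3 * T_c, where the exponential has
#'   decayed below 5% of `K`).
#' @param trace_lifetime Lifetime of a stored trace in epochs (6); a trace is
#'   erased once it is more than `trace_lifetime` epochs old.
#' @param c Recency-softening constant in epochs (1) in the trace weighting
#'   `tr_k / (t - t_k + c)`.
#' @param delta EMA rate of the per-synapse trace-history average `Avg_tr`
#'   (default 0.001, averaging over thousands of movement cycles).
#' @param d_tar Homeostatic step size (0.0001) multiplying a cell's target
#'   input sum up or down each epoch.
#' @param rate_ema EMA rate per epoch of the firing-rate estimate the
#'   homeostatic rule compares against its target (default 0.005).
#' @param avg_floor Numerical floor for `Avg_tr` in the normalization ratio
#'   (default 4e-5 = `delta * K`, the asymptotic average of a synapse tagged
#'   once per EMA memory), preventing overflow for synapses whose trace
#'   history has fully decayed.
#' @param norm_cap Upper bound on the normalization ratio `|Sum_tr| / Avg_tr`
#'   (default 20): rarely-tagged synapses still learn much faster than
#'   chronically tagged ones, but boundedly so.
#' @param factor_min,factor_max Bounds on each per-trace multiplicative weight
#'   factor `1 + (W_i0/W_i) * Delta_k` (defaults 0.5 and 2): one trace can at
#'   most double or halve a weight on a single reward event, keeping the
#'   multiplicative update scheme away from sign flips and collapse.
#' @param lambda_in Learning rate of the immediate (non-rewarded) STDP on the
#'   input projection: the trace value is added to the weight scaled by
#'   `lambda_in` (default 1).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(K = 0.04, T_c = 40, pairing_window = 120,
                        trace_lifetime = 6, c = 1, delta = 0.001,
                        d_tar = 1e-4, rate_ema = 0.005, avg_floor = 4e-5,
                        norm_cap = 20, factor_min = 0.5, factor_max = 2,
                        lambda_in = 1) {
  stopifnot(K > 0, T_c > 0, trace_lifetime >= 1, delta > 0, delta < 1,
            pairing_window > 0, c > 0, d_tar >= 0, norm_cap >= 1,
            factor_min > 0, factor_max > 1)
  structure(list(K = K, T_c = T_c, pairing_window = pairing_window,
                 trace_lifetime = trace_lifetime, c = c, delta = delta,
                 d_tar = d_tar, rate_ema = rate_ema, avg_floor = avg_floor,
                 norm_cap = norm_cap, factor_min = factor_min,
                 factor_max = factor_max, lambda_in = lambda_in),
            class = "stdp_params")
}

#' Value of an STDP trace for one spike pairing
#'
#' `tr = +K exp(-|dt|/T_c)` when the postsynaptic spike follows (or coincides
#' with) the presynaptic spike, `-K exp(-|dt|/T_c)` when it precedes it.
#' Pairings outside the pairing window create no trace (value 0).
#'
#' @param t_pre,t_post Spike times in ms (vectors recycle).
#' @param params An [stdp_params()] object.
#' @return Signed trace value(s); 0 outside the pairing window.
#' @export
stdp_trace_value <- function(t_pre, t_post, params = stdp_params()) {
  dt <- t_post - t_pre
  val <- ifelse(dt >= 0, params$K, -params$K) * exp(-abs(dt) / params$T_c)
  val[abs(dt) > params$pairing_window] <- 0
  val
}

#' All-to-all spike pairings within the STDP window
#'
#' Every presynaptic spike is compared with every postsynaptic spike; each
#' pair closer than the pairing window contributes one trace.
#'
#' @param pre_spikes,post_spikes Time-ordered spike times in ms.
#' @param params An [stdp_params()] object.
#' @return A data frame with columns `t_pre`, `t_post`, `value` (one row per
#'   pairing inside the window).
#' @export
collect_pairings <- function(pre_spikes, post_spikes, params = stdp_params()) {
  if (length(pre_spikes) == 0 || length(post_spikes) == 0) {
    return(data.frame(t_pre = numeric(0), t_post = numeric(0),
                      value = numeric(0)))
  }
  g <- expand.grid(t_pre = pre_spikes, t_post = post_spikes,
                   KEEP.OUT.ATTRS = FALSE)
  keep <- abs(g$t_post - g$t_pre) <= params$pairing_window
  g <- g[keep, , drop = FALSE]
  g$value <- stdp_trace_value(g$t_pre, g$t_post, params)
  rownames(g) <- NULL
  g
}

#' Recency-weighted sum of a synapse's live traces
#'
#' `Sum_tr = sum_k tr_k / (t - t_k + c)` with times in epoch units; a trace
#' created this epoch is weighted by `1/c`.
#'
#' @param values Trace values `tr_k`.
#' @param t_k Creation epochs of the traces.
#' @param t_now Current epoch.
#' @param c Recency constant in epochs (default 1).
#' @return The weighted sum (0 for no traces).
#' @export
sum_traces <- function(values, t_k, t_now, c = 1) {
  if (length(values) == 0) return(0)
  sum(values / (t_now - t_k + c))
}

#' Homeostatic adjustment of target input sums
#'
#' Each epoch, a cell firing below its target rate has its target input sum
#' multiplied by `1 + d_tar`; above target, by `1 - d_tar`; at exact equality
#' it is unchanged. Rates are exponential moving averages of per-epoch spike
#' counts.
#'
#' @param w_target Current target input sum(s).
#' @param rate Estimated firing rate(s) (same units as `target_rate`).
#' @param target_rate Target firing rate(s).
#' @param d_tar Step size (default 1e-4).
#' @return Updated target sum(s).
#' @export
homeostatic_update <- function(w_target, rate, target_rate, d_tar = 1e-4) {
  w_target * ifelse(rate < target_rate, 1 + d_tar,
                    ifelse(rate > target_rate, 1 - d_tar, 1))
}

#' Heterosynaptic rescaling of a cell's incoming weights
#'
#' Multiplies every incoming excitatory weight by `S_f = w_target / sum(w)` so
#' the input sum equals the target exactly. This is the compensatory rule that
#' forces synapses on the same postsynaptic cell to compete: whenever one
#' input grows, all its siblings shrink.
#'
#' @param w Incoming excitatory weights (non-negative, positive sum).
#' @param w_target Target input sum.
#' @return The rescaled weights, summing to `w_target` to machine precision.
#' @export
heterosynaptic_rescale <- function(w, w_target) {
  s <- sum(w)
  if (s <= 0) stop("degenerate cell: incoming weight sum is not positive")
  w * (w_target / s)
}

#' Immediate non-rewarded STDP on one cell's incoming weights
#'
#' Applies scripted STDP events to a postsynaptic cell's incoming weight
#' vector in time order: each event adds `lambda_in * tr` to the tagged
#' weight, clips to `[0, w_max]`, and (when heterosynaptic balancing is
#' active) rescales all incoming weights back to the cell's target sum, so
#' sibling inputs compensate for every change.
#'
#' @param w Incoming weight vector of the cell.
#' @param events A data frame (or list) with `slot` (index into `w`) and
#'   `value` (trace values), ordered by event time.
#' @param w_max Hard upper limit on a single weight.
#' @param w_target Target input sum of the cell.
#' @param params An [stdp_params()] object (uses `lambda_in`).
#' @param rescale Apply heterosynaptic rescaling after each event?
#' @return The updated weight vector.
#' @export
apply_unrewarded_stdp <- function(w, events, w_max, w_target,
                                  params = stdp_params(), rescale = TRUE) {
  n_ev <- length(events$slot)
  for (k in seq_len(n_ev)) {
    s <- events$slot[k]
    w[s] <- min(max(w[s] + params$lambda_in * events$value[k], 0), w_max)
    if (rescale) w <- heterosynaptic_rescale(w, w_target)
  }
  w
}

#' Create an empty eligibility-trace store
#'
#' Traces of the hidden-to-output projection are timestamped at epoch
#' resolution and indexed by the linear synapse index of the weight matrix.
#'
#' @param n_syn Number of hidden-to-output synapses.
#' @return An object of class `trace_store`.
#' @export
new_trace_store <- function(n_syn) {
  structure(list(idx = integer(0), value = numeric(0), t_k = numeric(0),
                 n_syn = as.integer(n_syn)),
            class = "trace_store")
}

#' Add traces to a store
#' @param store A [new_trace_store()] object.
#' @param idx Linear synapse indices.
#' @param value Trace values.
#' @param t_k Creation epoch (scalar or vector).
#' @return The updated store.
#' @export
add_traces <- function(store, idx, value, t_k) {
  store$idx <- c(store$idx, as.integer(idx))
  store$value <- c(store$value, value)
  store$t_k <- c(store$t_k, rep_len(t_k, length(idx)))
  store
}

#' Erase expired traces
#'
#' A trace lives for `lifetime` epochs after its creation: at age
#' `lifetime + 1` it is gone.
#'
#' @param store A trace store.
#' @param t_now Current epoch.
#' @param lifetime Lifetime in epochs (default 6).
#' @return The pruned store.
#' @export
prune_traces <- function(store, t_now, lifetime = 6) {
  keep <- (t_now - store$t_k) <= lifetime
  store$idx <- store$idx[keep]
  store$value <- store$value[keep]
  store$t_k <- store$t_k[keep]
  store
}

#' Create the trace-history normalizer state
#'
#' Tracks, per synapse, the exponential moving average `Avg_tr` of the
#' magnitude of the recency-weighted trace sum `Sum_tr`. The EMA starts at the
#' first nonzero `|Sum_tr|` a synapse produces; until then the normalization
#' ratio `|Sum_tr| / Avg_tr` is clamped to 1 (unbiased early learning, no
#' division by zero).
#'
#' @param n_syn Number of synapses.
#' @return A list with `avg` (numeric) and `started` (logical).
#' @export
new_trace_normalizer <- function(n_syn) {
  list(avg = numeric(n_syn), started = logical(n_syn))
}

#' Reward-gated application of stored STDP traces
#'
#' Converts the live eligibility traces into multiplicative weight changes of
#' the hidden-to-output projection when a reward or punishment signal `s_rp`
#' arrives:
#' \deqn{W_{ij} \leftarrow W_{ij} \prod_k (1 + (W_{i0}/W_i)\,\Delta_k),\quad
#'   \Delta_k = s_{rp} \frac{tr_k}{t - t_k + c}
#'   \frac{Sum_{tr}}{Avg_{tr}}}
#' The factor `W_i0 / W_i` (initial over current total output of the
#' presynaptic hidden cell) damps growth of cells that already dominate
#' (output balancing); the ratio `|Sum_tr| / Avg_tr` damps synapses whose
#' trace history is chronically strong (trace normalization; the ratio is
#' bounded by `norm_cap` and the per-trace factor by
#' `[factor_min, factor_max]`, see [stdp_params()]). Updated weights are
#' clipped to `[0, w_max]`. `Avg_tr` is then advanced one EMA step for every
#' synapse, using `|Sum_tr| = 0` where no traces are live.
#'
#' @param w_out Hidden-by-output weight matrix.
#' @param store Trace store (live traces; prune first).
#' @param normalizer State from [new_trace_normalizer()].
#' @param w_i0 Initial total output per hidden cell.
#' @param s_rp Reward scaling factor (+1 reward, -0.5 toxic food, -0.1 / -0.01
#'   foodless moves; see [reward_for()]).
#' @param t_now Current epoch.
#' @param params An [stdp_params()] object.
#' @param w_max Hard upper limit per weight.
#' @param output_balancing Apply the `W_i0 / W_i` factor?
#' @param trace_normalization Apply the `Sum_tr / Avg_tr` factor?
#' @return A list with the updated `w_out` and `normalizer`.
#' @export
apply_reward <- function(w_out, store, normalizer, w_i0, s_rp, t_now,
                         params = stdp_params(), w_max = Inf,
                         output_balancing = TRUE, trace_normalization = TRUE) {
  n_syn <- length(w_out)
  n_hid <- nrow(w_out)
  sum_tr <- numeric(n_syn)
  if (length(store$idx) > 0) {
    contrib <- store$value / (t_now - store$t_k + params$c)
    sum_tr <- accumulate_by_index_cpp(store$idx, contrib, n_syn)
    sids <- unique(store$idx)

    ratio <- rep(1, length(store$idx))
    if (trace_normalization) {
      started <- normalizer$started[store$idx]
      r <- abs(sum_tr[store$idx[started]]) /
        pmax(normalizer$avg[store$idx[started]], params$avg_floor)
      ratio[started] <- pmin(r, params$norm_cap)
    }
    balance <- rep(1, length(store$idx))
    if (output_balancing) {
      w_i <- rowSums(w_out)
      hid <- ((store$idx - 1L) %% n_hid) + 1L
      balance <- w_i0[hid] / pmax(w_i[hid], .Machine$double.eps)
    }
    fac <- pmin(pmax(1 + balance * s_rp * contrib * ratio,
                     params$factor_min), params$factor_max)
    lf <- accumulate_by_index_cpp(store$idx, log(fac), n_syn)
    w_out[sids] <- pmin(pmax(w_out[sids] * exp(lf[sids]), 0), w_max)
  }
  upd <- normalizer$started
  normalizer$avg[upd] <- normalizer$avg[upd] * (1 - params$delta) +
    params$delta * abs(sum_tr[upd])
  fresh <- !normalizer$started & sum_tr != 0
  normalizer$avg[fresh] <- abs(sum_tr[fresh])
  normalizer$started[fresh] <- TRUE
  list(w_out = w_out, normalizer = normalizer)
}
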