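#' Configuration of the spiking foraging network
#'
#' Assembles sizes, rates, plasticity constants and mechanism switches for the
#' feed-forward architecture: a 7x7 input layer driven by the visual field, a
#' 28x28 hidden layer wired to `fan_in` random inputs per cell (non-rewarded
#' STDP), and a 3x3 output layer receiving all-to-all connections from the
#' hidden layer (rewarded STDP). Every mechanism the model depends on can be
#' ablated independently for the mechanism studies.
#'
#' @param n_input,n_hidden,n_output Layer sizes (defaults 49, 784, 9).
#' @param fan_in Number of input cells wired to each hidden cell (default 9).
#' @param epoch_steps Steps per movement cycle (600; one step is 0.5 ms).
#' @param step_ms Duration of one map step in ms (0.5).
#' @param target_rate_hidden,target_rate_output Homeostatic target firing
#'   rates in Hz (defaults 0.4 and 5/3, i.e. 0.12 and 0.5 spikes per epoch).
#' @param kappa_hidden,kappa_output Layer excitability gains applied to the
#'   normalized conductance increments; calibrated so the untrained network
#'   responds to typical stimuli at roughly the target rates.
#' @param w_in_cv Coefficient of variation of the initial (truncated-normal)
#'   input-to-hidden weights (default 0.3).
#' @param pulse,pulse_steps Stimulation pulse delivered to input cells whose
#'   visual-field position holds food: `i_ext = pulse` for `pulse_steps`
#'   consecutive steps at epoch start (defaults 1.0 and 2, evoking exactly one
#'   spike).
#' @param inhibition_in,inhibition_out Mirrored feed-forward inhibition onto
#'   the hidden / output layer. `inhibition_in = NULL` resolves by task in
#'   [train()]: on for the single-food task, off for the pattern task.
#' @param heterosynaptic Input-side heterosynaptic balancing (rescale every
#'   cell's incoming sum to its homeostatic target after each change).
#' @param output_balancing The `W_i0 / W_i` damping of rewarded updates.
#' @param output_sum_fixed Hold each hidden cell's total outgoing strength
#'   constant (the compensation rule used only when both balancing rules are
#'   ablated).
#' @param trace_normalization The `Sum_tr / Avg_tr` trace-history
#'   normalization of rewarded updates.
#' @param homeostatic_hidden,homeostatic_output Homeostatic target-rate
#'   scaling per layer.
#' @param plastic_in,plastic_out Master switches for non-rewarded STDP
#'   (input projection) and rewarded STDP (output projection).
#' @param w_max_in_factor,w_max_out_factor Hard caps on single weights, in
#'   multiples of the empirically measured single-input spike threshold.
#'   `w_max_in_factor = NULL` resolves by task in [train()]: 1.5 for the
#'   single-food task (a mature synapse can relay an isolated food position
#'   on its own) and 0.6 for the pattern task (no single input may fire a
#'   hidden cell, the constraint that forces pair detection). Standalone
#'   [build_network()] uses 1.5.
#' @param conductance_norm Denominator of the synaptic-increment normalization
#'   `g / W_j`: `"initial"` (the cell's initial target input sum, a constant
#'   reference; default) or `"current"` (the running homeostatic target).
#' @param neuron,synapse,stdp Parameter objects ([neuron_params()],
#'   [synapse_params()], [stdp_params()]). `synapse$release_cv` is the
#'   release-noise amplitude `R` swept in the noise experiments.
#' @return An object of class `forage_config`.
#' @export
network_config <- function(n_input = 49L, n_hidden = 784L, n_output = 9L,
                           fan_in = 9L, epoch_steps = 600L, step_ms = 0.5,
                           target_rate_hidden = 0.4,
                           target_rate_output = 5 / 3,
                           kappa_hidden = 0.27, kappa_output = 5,
                           w_in_cv = 0.3, pulse = 1.0, pulse_steps = 2L,
                           inhibition_in = NULL, inhibition_out = TRUE,
                           heterosynaptic = TRUE, output_balancing = TRUE,
                           output_sum_fixed = FALSE,
                           trace_normalization = TRUE,
                           homeostatic_hidden = TRUE,
                           homeostatic_output = TRUE,
                           plastic_in = TRUE, plastic_out = TRUE,
                           w_max_in_factor = NULL, w_max_out_factor = 1.5,
                           conductance_norm = c("initial", "current"),
                           neuron = neuron_params(),
                           synapse = synapse_params(),
                           stdp = stdp_params()) {
  stopifnot(fan_in <= n_input, epoch_steps > 0)
  structure(list(n_input = as.integer(n_input),
                 n_hidden = as.integer(n_hidden),
                 n_output = as.integer(n_output), fan_in = as.integer(fan_in),
                 epoch_steps = as.integer(epoch_steps), step_ms = step_ms,
                 target_rate_hidden = target_rate_hidden,
                 target_rate_output = target_rate_output,
                 kappa_hidden = kappa_hidden, kappa_output = kappa_output,
                 w_in_cv = w_in_cv, pulse = pulse,
                 pulse_steps = as.integer(pulse_steps),
                 inhibition_in = inhibition_in,
                 inhibition_out = inhibition_out,
                 heterosynaptic = heterosynaptic,
                 output_balancing = output_balancing,
                 output_sum_fixed = output_sum_fixed,
                 trace_normalization = trace_normalization,
                 homeostatic_hidden = homeostatic_hidden,
                 homeostatic_output = homeostatic_output,
                 plastic_in = plastic_in, plastic_out = plastic_out,
                 w_max_in_factor = w_max_in_factor,
                 w_max_out_factor = w_max_out_factor,
                 conductance_norm = match.arg(conductance_norm),
                 neuron = neuron, synapse = synapse, stdp = stdp),
            class = "forage_config")
}

#' Build a network from a configuration
#'
#' Wires each hidden cell to `fan_in` distinct input cells chosen uniformly at
#' random, draws input-to-hidden weights from a positive truncated normal
#' (then balanced to each cell's target input sum), sets hidden-to-output
#' weights uniform, records the homeostatic targets and initial output sums,
#' measures the single-input spike threshold that anchors the hard weight
#' caps, and computes the mirrored inhibitory weights. All neurons start at
#' the resting fixed point.
#'
#' @param config A [network_config()] object.
#' @param seed Integer seed controlling wiring and initial weights.
#' @return An object of class `forage_network`.
#' @export
build_network <- function(config = network_config(), seed = 1L) {
  set.seed(seed)
  cf <- config
  n_in <- cf$n_input; n_hid <- cf$n_hidden; n_out <- cf$n_output
  fan <- cf$fan_in

  wiring <- vapply(seq_len(n_hid),
                   function(j) sort(sample.int(n_in, fan)),
                   integer(fan))
  m <- 1 / fan
  w_in <- matrix(stats::rnorm(fan * n_hid, m, cf$w_in_cv * m), fan, n_hid)
  while (any(w_in <= 0)) {
    bad <- w_in <= 0
    w_in[bad] <- stats::rnorm(sum(bad), m, cf$w_in_cv * m)
  }
  w_tgt_hid <- rep(1, n_hid)
  w_in <- w_in * rep(w_tgt_hid / colSums(w_in), each = fan)
  w_tgt_out <- rep(1, n_out)
  w_out <- matrix(w_tgt_out[1] / n_hid, n_hid, n_out)

  # CSR of the input->hidden projection, ordered by presynaptic input cell
  pre <- as.vector(wiring)
  hid <- rep(seq_len(n_hid), each = fan)
  ord <- order(pre)
  in_ptr <- c(0L, cumsum(tabulate(pre, n_in)))
  slot_of <- matrix(0L, n_in, n_hid)
  slot_of[cbind(pre, hid)] <- rep(seq_len(fan), n_hid)

  g_star <- spike_threshold(cf$neuron, cf$synapse, max_steps = cf$epoch_steps)
  rest <- rulkov_rest(cf$neuron)
  n <- n_in + n_hid + n_out

  net <- structure(list(
    config = cf, n = n,
    wiring = wiring, slot_of = slot_of,
    csr_ptr = as.integer(in_ptr), csr_tgt = as.integer(hid[ord]),
    csr_pre = as.integer(pre[ord]), csr_widx = ord,
    w_in = w_in, w_out = w_out,
    w_tgt_hid = w_tgt_hid, w_tgt_out = w_tgt_out,
    w_ref_hid = w_tgt_hid, w_ref_out = w_tgt_out,
    w_i0_out = rowSums(w_out),
    g_star = g_star,
    w_max_in = (if (is.null(cf$w_max_in_factor)) 1.5 else cf$w_max_in_factor) *
      g_star / cf$kappa_hidden,
    w_max_out = cf$w_max_out_factor * g_star / cf$kappa_output,
    wbar_in = numeric(n_in), wbar_hid = numeric(n_hid),
    v = rep(rest$v, n), v_prev = rep(rest$v_prev, n),
    i_slow = rep(rest$i_slow, n),
    g_exc = numeric(n), g_inh = numeric(n),
    traces = new_trace_store(n_hid * n_out),
    normalizer = new_trace_normalizer(n_hid * n_out),
    rate_hid = numeric(n_hid), rate_out = numeric(n_out),
    epoch = 0L,
    prev_spikes = cbind(cell = integer(0), step = integer(0))
  ), class = "forage_network")
  update_mirrors(net)
}

# Recompute the mirrored inhibition weights from the excitatory weights.
update_mirrors <- function(net) {
  n_in <- net$config$n_input
  cnts <- tabulate(net$csr_pre, n_in)
  sums <- accumulate_by_index_cpp(net$csr_pre,
                                  as.vector(net$w_in)[net$csr_widx], n_in)
  net$wbar_in <- ifelse(cnts > 0, sums / pmax(cnts, 1L), 0)
  net$wbar_hid <- rowMeans(net$w_out)
  net
}

# Per-cell normalization scale of conductance increments: kappa / W_ref
# ("initial") or kappa / W_j0(t) ("current").
conductance_scales <- function(net) {
  cf <- net$config
  if (cf$conductance_norm == "initial") {
    list(hid = cf$kappa_hidden / net$w_ref_hid,
         out = cf$kappa_output / net$w_ref_out)
  } else {
    list(hid = cf$kappa_hidden / net$w_tgt_hid,
         out = cf$kappa_output / net$w_tgt_out)
  }
}

#' Simulate one epoch of network dynamics
#'
#' Delivers the stimulation pulse to the input cells flagged by `stimulus`,
#' integrates all neurons and kinetic synapses (with mirrored feed-forward
#' inhibition and multiplicative release noise) for `epoch_steps` map steps,
#' applies non-rewarded STDP to the input projection (each pairing acts
#' immediately, followed by heterosynaptic rescaling of the affected cell),
#' and stores hidden-to-output pairings as eligibility traces for later reward.
#' Output spike counts are additionally tallied over the first half of the
#' epoch, the window that drives the movement decision. Membrane and
#' conductance state carries over between epochs (an epoch is long enough to
#' return to rest); `record$at_rest` flags epochs that started away from rest.
#'
#' @param net A [build_network()] object.
#' @param stimulus Logical vector of length `n_input` (the visual field).
#' @param seed Integer seed for the release noise of this epoch; drawn from
#'   the session RNG when `NULL`.
#' @return A list with the updated `net` and a `record` (spike counts per
#'   cell, first-half output counts, spike times, stimulus).
#' @export
run_epoch <- function(net, stimulus, seed = NULL) {
  cf <- net$config
  n_in <- cf$n_input; n_hid <- cf$n_hidden; n_out <- cf$n_output
  stopifnot(length(stimulus) == n_in)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)
  e <- net$epoch + 1L

  sc <- conductance_scales(net)
  in_w_norm <- as.vector(net$w_in)[net$csr_widx] * sc$hid[net$csr_tgt]
  in_wbar_norm <- net$wbar_in[net$csr_pre] * sc$hid[net$csr_tgt]
  w_out_norm <- net$w_out * rep(sc$out, each = n_hid)
  wbar_out_norm <- outer(net$wbar_hid, sc$out)
  inh_in <- isTRUE(cf$inhibition_in) || is.null(cf$inhibition_in)

  at_rest <- max(abs(net$g_exc), abs(net$g_inh)) < 1e-9
  res <- epoch_dynamics_cpp(
    net$v, net$v_prev, net$i_slow, net$g_exc, net$g_inh,
    which(stimulus), n_in, n_hid, n_out,
    net$csr_ptr, net$csr_tgt, in_w_norm, in_wbar_norm,
    w_out_norm, wbar_out_norm,
    cf$neuron$alpha, cf$neuron$mu, cf$neuron$sigma, cf$neuron$beta_e,
    cf$neuron$sigma_e, cf$synapse$gamma, cf$synapse$release_cv,
    cf$synapse$v_rp_exc, cf$synapse$v_rp_inh,
    inh_in, isTRUE(cf$inhibition_out),
    as.integer(round(cf$synapse$inh_delay_ms / cf$step_ms)),
    cf$epoch_steps, cf$epoch_steps %/% 2L,
    cf$pulse, cf$pulse_steps, seed)

  net$v <- res$v; net$v_prev <- res$v_prev; net$i_slow <- res$i_slow
  net$g_exc <- res$g_exc; net$g_inh <- res$g_inh
  net$epoch <- e

  base <- (e - 1L) * cf$epoch_steps
  cur <- cbind(cell = res$spike_cell, step = base + res$spike_step)
  all_sp <- rbind(net$prev_spikes, cur)
  win_steps <- cf$stdp$pairing_window / cf$step_ms

  in_sp <- all_sp[all_sp[, 1] <= n_in, , drop = FALSE]
  hid_sp <- all_sp[all_sp[, 1] > n_in & all_sp[, 1] <= n_in + n_hid, ,
                   drop = FALSE]
  out_sp <- all_sp[all_sp[, 1] > n_in + n_hid, , drop = FALSE]

  if (cf$plastic_in && nrow(in_sp) > 0 && nrow(hid_sp) > 0) {
    net <- stdp_input_projection(net, in_sp, hid_sp, base, win_steps)
  }
  if (cf$plastic_out && nrow(hid_sp) > 0 && nrow(out_sp) > 0) {
    net <- record_output_traces(net, hid_sp, out_sp, base, win_steps, e)
  }
  net$prev_spikes <- cur[cur[, 2] > base + cf$epoch_steps - win_steps, ,
                         drop = FALSE]

  record <- list(epoch = e, counts = res$counts, half_out = res$half_out,
                 spikes = cur, stimulus = stimulus, at_rest = at_rest,
                 hid_spikes = sum(res$counts[(n_in + 1):(n_in + n_hid)]),
                 out_spikes = sum(res$counts[(n_in + n_hid + 1):net$n]))
  list(net = net, record = record)
}

# Immediate non-rewarded STDP on the input->hidden projection: all wired
# pairings whose later spike falls in the current epoch are applied in event
# order, each followed by heterosynaptic rescaling of the postsynaptic cell.
stdp_input_projection <- function(net, in_sp, hid_sp, base, win_steps) {
  cf <- net$config
  na <- nrow(in_sp)
  nb <- nrow(hid_sp)
  a <- rep.int(seq_len(na), nb)
  b <- rep(seq_len(nb), each = na)
  t_pre <- in_sp[a, 2]
  t_post <- hid_sp[b, 2]
  i_cell <- in_sp[a, 1]
  h_cell <- hid_sp[b, 1] - cf$n_input
  slot <- net$slot_of[cbind(i_cell, h_cell)]
  t_ev <- pmax(t_pre, t_post)
  keep <- slot > 0L & abs(t_post - t_pre) <= win_steps & t_ev > base
  if (!any(keep)) return(net)
  value <- stdp_trace_value(t_pre[keep] * cf$step_ms,
                            t_post[keep] * cf$step_ms, cf$stdp)
  h <- h_cell[keep]
  slot <- slot[keep]
  t_ev <- t_ev[keep]
  ord <- order(h, t_ev)
  h <- h[ord]; slot <- slot[ord]; value <- value[ord]
  bounds <- c(0L, which(diff(h) != 0L), length(h))
  for (k in seq_len(length(bounds) - 1L)) {
    ix <- (bounds[k] + 1L):bounds[k + 1L]
    hc <- h[ix[1L]]
    net$w_in[, hc] <- apply_unrewarded_stdp(
      net$w_in[, hc], list(slot = slot[ix], value = value[ix]),
      net$w_max_in, net$w_tgt_hid[hc], cf$stdp,
      rescale = cf$heterosynaptic)
  }
  update_mirrors(net)
}

# Store hidden->output pairings as eligibility traces (epoch-resolution
# timestamps; values at full step resolution).
record_output_traces <- function(net, hid_sp, out_sp, base, win_steps, e) {
  cf <- net$config
  na <- nrow(hid_sp)
  nb <- nrow(out_sp)
  a <- rep.int(seq_len(na), nb)
  b <- rep(seq_len(nb), each = na)
  t_pre <- hid_sp[a, 2]
  t_post <- out_sp[b, 2]
  keep <- abs(t_post - t_pre) <= win_steps & pmax(t_pre, t_post) > base
  if (!any(keep)) return(net)
  value <- stdp_trace_value(t_pre[keep] * cf$step_ms,
                            t_post[keep] * cf$step_ms, cf$stdp)
  h <- hid_sp[a[keep], 1] - cf$n_input
  o <- out_sp[b[keep], 1] - cf$n_input - cf$n_hidden
  idx <- h + (o - 1L) * cf$n_hidden
  net$traces <- add_traces(net$traces, idx, value, e)
  net
}

#' End-of-epoch homeostatic housekeeping
#'
#' Updates the firing-rate estimates (EMA of per-epoch spike counts), applies
#' the homeostatic target-scaling step to every hidden and output cell,
#' enforces the (possibly new) targets by heterosynaptic rescaling, prunes
#' expired eligibility traces, and refreshes the mirrored inhibitory weights.
#'
#' @param net A network (after [run_epoch()] and any reward application).
#' @param counts Per-cell spike counts of the finished epoch
#'   (`record$counts`).
#' @return The updated network.
#' @export
epoch_housekeeping <- function(net, counts) {
  cf <- net$config
  n_in <- cf$n_input; n_hid <- cf$n_hidden; n_out <- cf$n_output
  a <- cf$stdp$rate_ema
  cnt_hid <- counts[(n_in + 1):(n_in + n_hid)]
  cnt_out <- counts[(n_in + n_hid + 1):net$n]
  net$rate_hid <- (1 - a) * net$rate_hid + a * cnt_hid
  net$rate_out <- (1 - a) * net$rate_out + a * cnt_out

  epoch_s <- cf$epoch_steps * cf$step_ms / 1000
  if (cf$homeostatic_hidden) {
    net$w_tgt_hid <- homeostatic_update(net$w_tgt_hid, net$rate_hid,
                                        cf$target_rate_hidden * epoch_s,
                                        cf$stdp$d_tar)
    # feasibility bound: a target above 90% of fan_in * w_max could only be
    # met with every input pinned at the hard cap
    net$w_tgt_hid <- pmin(pmax(net$w_tgt_hid, 0.1),
                          0.9 * cf$fan_in * net$w_max_in)
  }
  if (cf$homeostatic_output) {
    net$w_tgt_out <- homeostatic_update(net$w_tgt_out, net$rate_out,
                                        cf$target_rate_output * epoch_s,
                                        cf$stdp$d_tar)
    net$w_tgt_out <- pmin(pmax(net$w_tgt_out, 0.1),
                          0.9 * n_hid * net$w_max_out)
  }
  if (cf$heterosynaptic) {
    net$w_in <- net$w_in *
      rep(net$w_tgt_hid / colSums(net$w_in), each = cf$fan_in)
    net$w_out <- net$w_out *
      rep(net$w_tgt_out / colSums(net$w_out), each = n_hid)
  }
  if (cf$output_sum_fixed) {
    net$w_out <- net$w_out * (net$w_i0_out / rowSums(net$w_out))
  }
  net$traces <- prune_traces(net$traces, net$epoch, cf$stdp$trace_lifetime)
  update_mirrors(net)
}

#' Apply a reward or punishment signal to a network
#'
#' Thin wrapper around [apply_reward()] operating on the network's own trace
#' store, normalizer, and hidden-to-output weights; honors the network's
#' output-balancing and trace-normalization switches.
#'
#' @param net A network.
#' @param s_rp Reward scaling factor (see [reward_for()]).
#' @return The updated network.
#' @export
reward_network <- function(net, s_rp) {
  cf <- net$config
  if (!cf$plastic_out) return(net)
  res <- apply_reward(net$w_out, net$traces, net$normalizer, net$w_i0_out,
                      s_rp, net$epoch, cf$stdp, net$w_max_out,
                      output_balancing = cf$output_balancing,
                      trace_normalization = cf$trace_normalization)
  net$w_out <- res$w_out
  net$normalizer <- res$normalizer
  net
}
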