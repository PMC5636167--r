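test_that("conductance update decays geometrically and jumps on spikes", {
  sp <- synapse_params(gamma = 0.9, release_cv = 0)
  expect_equal(conductance_step(0, 1, 1, FALSE, 0, sp), 0)
  expect_equal(conductance_step(1, 1, 1, FALSE, 0, sp), 0.9)
  expect_equal(conductance_step(0, 2, 1, TRUE, 0, sp), 2)
  expect_equal(conductance_step(1, 2, 4, TRUE, 0, sp), 0.9 + 0.5)
  expect_error(conductance_step(0, 1, 0, TRUE, 0, sp), "positive")
})

test_that("release noise scales the increment linearly within [1-R, 1+R]", {
  sp <- synapse_params(release_cv = 0.12)
  expect_equal(conductance_step(0, 1, 1, TRUE, 1, sp), 1.12)
  expect_equal(conductance_step(0, 1, 1, TRUE, -1, sp), 0.88)
  expect_equal(conductance_step(0, 1, 1, TRUE, 0.5, sp), 1.06)
})

test_that("noisy increments in the epoch kernel are flat on [1-R, 1+R]", {
  # one input cell wired to one hidden cell, stimulated every epoch: each
  # presynaptic spike delivers one noisy conductance increment
  cfg <- network_config(n_input = 1L, n_hidden = 1L, n_output = 1L,
                        fan_in = 1L, inhibition_in = FALSE,
                        inhibition_out = FALSE, plastic_in = FALSE,
                        plastic_out = FALSE, epoch_steps = 40L)
  net <- build_network(cfg, seed = 1)
  rest <- rulkov_rest(cfg$neuron)
  incs <- numeric(400)
  for (k in seq_len(400)) {
    # restart every cell from rest so each epoch delivers one clean increment
    net$g_exc[] <- 0; net$g_inh[] <- 0
    net$v[] <- rest$v; net$v_prev[] <- rest$v_prev
    net$i_slow[] <- rest$i_slow
    st <- run_epoch(net, TRUE, seed = k)
    sp <- st$record$spikes
    in_step <- sp[sp[, 1] == 1, 2][1] - (k - 1) * 40
    # increment landed right after the input spike; undo the decay since then
    g_end <- st$net$g_exc[2]
    incs[k] <- g_end / cfg$synapse$gamma^(40 - in_step - 1)
    net <- st$net
  }
  w_norm <- net$w_in[1, 1] * cfg$kappa_hidden
  u <- incs / w_norm
  R <- cfg$synapse$release_cv
  expect_true(all(u >= 1 - R - 1e-9 & u <= 1 + R + 1e-9))
  expect_gt(diff(range(u)), 1.5 * R) # spread fills most of the band
  expect_equal(mean(u), 1, tolerance = 0.02)
})

test_that("synaptic current sign follows the reversal potential", {
  expect_equal(synaptic_current(1, 0, 0), 0)
  expect_equal(synaptic_current(2, -1, 0), 2)
  expect_equal(synaptic_current(1, -1, -1.1), -0.1)
})

test_that("mirrored inhibition equals the mean excitatory output", {
  expect_equal(mirror_inhibition(c(1, 1, 1)), 1)
  expect_equal(mirror_inhibition(c(0, 2)), 1)
  expect_error(mirror_inhibition(numeric(0)), "no excitatory outputs")
  # recomputed mirror tracks updated weights
  w <- runif(9)
  w2 <- heterosynaptic_rescale(w, 2)
  expect_equal(mirror_inhibition(w2), mean(w2))
})

test_that("total inhibitory output equals total excitatory output per cell", {
  net <- build_network(network_config(), seed = 2)
  n_out <- net$config$n_output
  # hidden cell mirrors: uniform weight to all outputs it excites
  expect_equal(net$wbar_hid * n_out, rowSums(net$w_out), tolerance = 1e-12)
  # input cell mirrors: uniform weight to each wired hidden target
  tgts <- tabulate(net$csr_pre, net$config$n_input)
  sums <- sapply(seq_len(net$config$n_input), function(i) {
    hs <- which(net$slot_of[i, ] > 0)
    sum(net$w_in[cbind(net$slot_of[i, hs], hs)])
  })
  expect_equal(net$wbar_in * tgts, sums, tolerance = 1e-12)
})

test_that("single-input spike threshold behaves as a threshold", {
  g <- spike_threshold()
  expect_gt(g, 0)
  p <- neuron_params(); sp <- synapse_params()
  sim <- function(g0) {
    st <- rulkov_rest(p); gg <- g0; n_spk <- 0L
    for (k in 1:600) {
      st <- rulkov_step(st, p, synaptic_current(gg, st$v, sp$v_rp_exc))
      n_spk <- n_spk + st$spiked
      gg <- gg * sp$gamma
    }
    n_spk
  }
  expect_equal(sim(0.99 * g), 0L)
  expect_gt(sim(1.01 * g), 0L)
})
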