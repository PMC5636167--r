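test_that("default architecture has the stated counts", {
  net <- build_network(network_config(), seed = 1)
  expect_equal(net$n, 842)
  expect_equal(length(net$w_in), 784 * 9) # input->hidden synapses
  expect_equal(length(net$w_out), 784 * 9) # hidden->output synapses
  expect_equal(dim(net$wiring), c(9, 784))
  # every hidden cell wired to distinct inputs
  expect_true(all(apply(net$wiring, 2, anyDuplicated) == 0))
  # input sums balanced to targets, output weights uniform
  expect_equal(colSums(net$w_in), net$w_tgt_hid, tolerance = 1e-12)
  expect_equal(length(unique(as.vector(net$w_out))), 1)
})

test_that("wiring and weights are reproducible by seed", {
  a <- build_network(network_config(), seed = 42)
  b <- build_network(network_config(), seed = 42)
  expect_identical(a$wiring, b$wiring)
  expect_identical(a$w_in, b$w_in)
  d <- build_network(network_config(), seed = 43)
  expect_false(identical(a$wiring, d$wiring))
})

test_that("full fan-in wires every hidden cell to the whole field", {
  cfg <- network_config(n_hidden = 16L, fan_in = 49L)
  net <- build_network(cfg, seed = 1)
  expect_true(all(apply(net$wiring, 2, function(x) all(sort(x) == 1:49))))
  expect_error(build_network(network_config(fan_in = 50L), seed = 1))
})

test_that("epoch dynamics: silent without stimulus, one spike per input", {
  cfg <- network_config()
  net <- build_network(cfg, seed = 3)
  st <- run_epoch(net, rep(FALSE, 49), seed = 1)
  expect_equal(sum(st$record$counts[1:49]), 0)
  expect_equal(st$record$hid_spikes, 0)
  expect_equal(st$record$out_spikes, 0)

  stim <- rep(FALSE, 49)
  stim[19] <- TRUE # one food NE of the agent
  st2 <- run_epoch(net, stim, seed = 2)
  expect_equal(st2$record$counts[19], 1) # that input fires exactly once
  expect_equal(sum(st2$record$counts[1:49]), 1)
})

test_that("epoch dynamics are reproducible for a fixed seed", {
  cfg <- network_config()
  net <- build_network(cfg, seed = 4)
  stim <- rep(FALSE, 49)
  stim[c(5, 19, 30, 44)] <- TRUE
  a <- run_epoch(net, stim, seed = 77)
  b <- run_epoch(net, stim, seed = 77)
  expect_identical(a$record$spikes, b$record$spikes)
  expect_identical(a$net$v, b$net$v)
  expect_identical(a$net$g_exc, b$net$g_exc)
})

test_that("input sums stay pinned to homeostatic targets through learning", {
  cfg <- network_config()
  net <- build_network(cfg, seed = 5)
  set.seed(5)
  wld <- init_world("single")
  for (e in 1:15) {
    st <- run_epoch(net, visual_field(wld))
    net <- reward_network(st$net, if (e %% 3 == 0) 1 else -0.1)
    net <- epoch_housekeeping(net, st$record$counts)
    mv <- apply_move(wld, sample.int(8, 1))
    wld <- mv$world
  }
  expect_equal(colSums(net$w_in), net$w_tgt_hid, tolerance = 1e-12)
  expect_equal(colSums(net$w_out), net$w_tgt_out, tolerance = 1e-12)
  expect_gt(length(net$traces$idx), 0) # pairings were stored
  expect_true(all(net$epoch - net$traces$t_k <= 6)) # expiry enforced
})

test_that("silent cells' homeostatic targets grow geometrically", {
  cfg <- network_config()
  net <- build_network(cfg, seed = 6)
  counts <- integer(net$n) # a fully silent epoch
  net$epoch <- 1L
  for (k in 1:5) net <- epoch_housekeeping(net, counts)
  expect_equal(net$w_tgt_hid, rep(1.0001^5, 784), tolerance = 1e-12)
  expect_equal(net$w_tgt_out, rep(1.0001^5, 9), tolerance = 1e-12)
})

test_that("unrewarded STDP potentiates the wired active input", {
  # strip the network to make pairing deterministic: no noise, no inhibition
  cfg <- network_config(synapse = synapse_params(release_cv = 0),
                        inhibition_in = FALSE, inhibition_out = FALSE,
                        plastic_out = FALSE)
  net <- build_network(cfg, seed = 7)
  # stimulate enough inputs to fire some hidden cells
  stim <- rep(FALSE, 49)
  stim[net$wiring[1:6, 1]] <- TRUE # 6 of hidden cell 1's inputs
  before <- net$w_in[, 1]
  st <- run_epoch(net, stim, seed = 1)
  hid_fired <- st$record$counts[49 + 1] > 0
  expect_true(hid_fired)
  after <- st$net$w_in[, 1]
  wired_active <- net$wiring[, 1] %in% which(stim)
  # potentiated synapses gained relative to inactive siblings
  expect_gt(min(after[wired_active] - before[wired_active]), 0)
  expect_lt(max(after[!wired_active] - before[!wired_active]), 0)
  expect_equal(sum(after), net$w_tgt_hid[1], tolerance = 1e-12)
})
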