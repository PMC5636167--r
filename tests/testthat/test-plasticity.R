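test_that("trace values follow the signed exponential window", {
  p <- stdp_params()
  expect_equal(stdp_trace_value(10, 10, p), 0.04)
  expect_equal(stdp_trace_value(10, 8, p), -0.04 * exp(-2 / 40))
  expect_equal(stdp_trace_value(0, 40, p), 0.04 * exp(-1))
  expect_equal(stdp_trace_value(0, 200, p), 0) # outside the window
})

test_that("pairings are collected all-to-all within the window", {
  p <- stdp_params()
  pr <- collect_pairings(10, 12, p)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$value, 0.04 * exp(-2 / 40))

  expect_equal(nrow(collect_pairings(numeric(0), 5, p)), 0)

  pr <- collect_pairings(c(0, 1), 2, p)
  expect_equal(nrow(pr), 2) # both pre spikes pair with the post spike
  # brute-force oracle: enumerate pairs by hand
  expected <- c(stdp_trace_value(0, 2, p), stdp_trace_value(1, 2, p))
  expect_equal(sort(pr$value), sort(expected))

  pr <- collect_pairings(c(0, 50), c(10, 300), p)
  expect_equal(nrow(pr), 2) # (0,10) and (50,10); both x-300 pairs are outside
})

test_that("scripted trace scenarios evaluate to their frozen expectations", {
  for (sc in make_trace_scenarios()) {
    got <- collect_pairings(sc$pre, sc$post, stdp_params())
    expect_equal(got, sc$expected, tolerance = 1e-12)
  }
})

test_that("recency-weighted trace sums match hand evaluation", {
  expect_equal(sum_traces(0.04, t_k = 5, t_now = 5), 0.04)
  expect_equal(sum_traces(0.04, t_k = 2, t_now = 5), 0.01)
  expect_equal(sum_traces(numeric(0), numeric(0), 5), 0)
  expect_equal(sum_traces(c(0.04, -0.02), c(5, 4), 5), 0.04 - 0.02 / 2)
})

test_that("homeostatic scaling multiplies targets by 1 +/- d_tar", {
  expect_equal(homeostatic_update(2, 0.1, 0.5), 2 * 1.0001)
  expect_equal(homeostatic_update(2, 0.9, 0.5), 2 * 0.9999)
  expect_equal(homeostatic_update(2, 0.5, 0.5), 2)
  expect_equal(homeostatic_update(c(1, 1), c(0, 1), 0.5),
               c(1.0001, 0.9999))
})

test_that("heterosynaptic rescaling restores the input sum exactly", {
  expect_equal(heterosynaptic_rescale(c(2, 2), 2), c(1, 1))
  w <- c(0.3, 0.7)
  expect_equal(heterosynaptic_rescale(w, 1), w)
  set.seed(7)
  for (k in 1:20) {
    w <- runif(9)
    tgt <- runif(1, 0.5, 3)
    expect_equal(sum(heterosynaptic_rescale(w, tgt)), tgt, tolerance = 1e-12)
  }
  expect_error(heterosynaptic_rescale(c(0, 0), 1), "degenerate")
})

test_that("immediate STDP conserves the input sum and respects the cap", {
  p <- stdp_params()
  w <- rep(0.5, 4)
  ev <- list(slot = 1L, value = 0.04)
  w2 <- apply_unrewarded_stdp(w, ev, w_max = 1, w_target = 2, p)
  expect_gt(w2[1], w[1] * 2 / sum(c(0.54, rep(0.5, 3)))) # tagged synapse up
  expect_true(all(w2[-1] < 0.5)) # siblings compensate down
  expect_equal(sum(w2), 2, tolerance = 1e-12)

  # cap binds before rescale
  w3 <- apply_unrewarded_stdp(c(0.99, 0.5), list(slot = 1L, value = 0.04),
                              w_max = 1, w_target = 1.49, p, rescale = FALSE)
  expect_equal(w3[1], 1)

  # zero events: identity
  w4 <- apply_unrewarded_stdp(w, list(slot = integer(0), value = numeric(0)),
                              1, 2, p)
  expect_identical(w4, w)
})

test_that("trace store prunes at the 6-epoch lifetime", {
  st <- new_trace_store(10)
  st <- add_traces(st, idx = 1L, value = 0.04, t_k = 1)
  for (e in 2:7) expect_equal(length(prune_traces(st, e)$idx), 1)
  expect_equal(length(prune_traces(st, 8)$idx), 0) # absent at epoch 1 + 7
})

test_that("reward application reproduces hand-evaluated factors", {
  p <- stdp_params()
  w0 <- matrix(0.25, 2, 2) # W_i = W_i0 = 0.5 per hidden cell
  w_i0 <- rowSums(w0)

  # single fresh trace, all normalizers at 1: factor exactly (1 + 0.04)
  st <- add_traces(new_trace_store(4), 1L, 0.04, t_k = 3)
  nr <- new_trace_normalizer(4)
  nr$avg[1] <- 0.04 # equals Sum_tr for a fresh trace
  nr$started[1] <- TRUE
  res <- apply_reward(w0, st, nr, w_i0, s_rp = 1, t_now = 3, p)
  expect_equal(res$w_out[1, 1], 0.25 * 1.04, tolerance = 1e-12)
  expect_equal(res$w_out[2:4], rep(0.25, 3)) # untagged unchanged

  # punishment at half magnitude: factor (1 - 0.02)
  res2 <- apply_reward(w0, st, nr, w_i0, s_rp = -0.5, t_now = 3, p)
  expect_equal(res2$w_out[1, 1], 0.25 * 0.98, tolerance = 1e-12)

  # an aged trace is discounted by 1 / (t - t_k + c)
  st3 <- add_traces(new_trace_store(4), 1L, 0.04, t_k = 1)
  nr3 <- nr
  nr3$avg[1] <- 0.04 / 4
  res3 <- apply_reward(w0, st3, nr3, w_i0, s_rp = 1, t_now = 4, p)
  expect_equal(res3$w_out[1, 1], 0.25 * 1.01, tolerance = 1e-12)

  # no live traces: weights unchanged, Avg_tr decays toward zero
  res4 <- apply_reward(w0, new_trace_store(4), nr, w_i0, 1, 5, p)
  expect_identical(res4$w_out, w0)
  expect_equal(res4$normalizer$avg[1], 0.04 * (1 - p$delta))
})

test_that("trace normalization damps chronically strong-trace synapses", {
  p <- stdp_params()
  w0 <- matrix(0.25, 2, 2)
  w_i0 <- rowSums(w0)
  st <- add_traces(new_trace_store(4), 1L, 0.04, t_k = 3)
  lo <- new_trace_normalizer(4)
  lo$avg[1] <- 0.02; lo$started[1] <- TRUE
  hi <- lo
  hi$avg[1] <- 0.08
  up_lo <- apply_reward(w0, st, lo, w_i0, 1, 3, p)$w_out[1, 1]
  up_hi <- apply_reward(w0, st, hi, w_i0, 1, 3, p)$w_out[1, 1]
  expect_gt(up_lo, up_hi) # larger Avg_tr means smaller potentiation
  # exact ratio of the increments: (0.04/0.02) / (0.04/0.08) = 4
  expect_equal((up_lo - 0.25) / (up_hi - 0.25), 4, tolerance = 1e-9)
})

test_that("output balancing scales the update by W_i0 / W_i exactly", {
  p <- stdp_params()
  w_i0 <- c(0.5, 0.5)
  st <- add_traces(new_trace_store(4), c(1L, 2L), c(0.04, 0.04), t_k = 3)
  nr <- new_trace_normalizer(4)
  nr$avg[1:2] <- 0.04; nr$started[1:2] <- TRUE
  # hidden cell 2 already doubled its total output
  w <- matrix(c(0.25, 0.5, 0.25, 0.5), 2, 2)
  res <- apply_reward(w, st, nr, w_i0, 1, 3, p)
  d1 <- res$w_out[1, 1] / w[1, 1] - 1 # balance 1
  d2 <- res$w_out[2, 1] / w[2, 1] - 1 # balance 0.5
  expect_equal(d1, 0.04, tolerance = 1e-12)
  expect_equal(d2, 0.02, tolerance = 1e-12)
  # disabled balancing treats both alike
  res0 <- apply_reward(w, st, nr, w_i0, 1, 3, p, output_balancing = FALSE)
  expect_equal(res0$w_out[2, 1] / w[2, 1] - 1, 0.04, tolerance = 1e-12)
})

test_that("negative reward with positive traces strictly decreases weights", {
  p <- stdp_params()
  w <- matrix(runif(6, 0.2, 0.4), 3, 2)
  st <- add_traces(new_trace_store(6), c(1L, 4L), c(0.04, 0.01), t_k = 2)
  nr <- new_trace_normalizer(6)
  res <- apply_reward(w, st, nr, rowSums(w), s_rp = -0.1, t_now = 2, p)
  expect_lt(res$w_out[1, 1], w[1, 1])
  expect_lt(res$w_out[1, 2], w[1, 2])
  expect_equal(res$w_out[c(2, 3, 5, 6)], w[c(2, 3, 5, 6)])
})

test_that("multiple traces on one synapse compound multiplicatively", {
  p <- stdp_params()
  w <- matrix(0.25, 2, 2)
  st <- add_traces(new_trace_store(4), c(1L, 1L), c(0.04, 0.02), t_k = 3)
  nr <- new_trace_normalizer(4)
  sum_tr <- 0.04 + 0.02
  nr$avg[1] <- sum_tr; nr$started[1] <- TRUE # normalization ratio 1
  res <- apply_reward(w, st, nr, rowSums(w), 1, 3, p)
  expect_equal(res$w_out[1, 1], 0.25 * 1.04 * 1.02, tolerance = 1e-12)
})
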