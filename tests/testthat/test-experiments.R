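# Experiment analysis helpers and light-weight behavioural checks.
# (The full experiment-level criteria live in test-acceptance.R.)

test_that("spikes_to_fire counts causally contributing input spikes", {
  # fabricate a recording: inputs (id 1) at 0,2,4 per presentation,
  # post (id 2) firing at different latencies
  rec <- structure(list(spikes = data.frame(
    time_ms = c(0, 2, 4, 3, 50, 52, 54, 100, 102, 104, 100),
    neuron_id = c(1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 2)),
    sizes = c(2)), class = "recording_set")
  stf <- spikes_to_fire(rec, c(0, 50, 100), input_ids = 1, post_ids = 2,
                        delay = 1)
  expect_equal(stf[1], 2L)        # post at 3: arrivals 1, 3 count; 5 not
  expect_true(is.na(stf[2]))      # no post spike: sentinel
  expect_equal(stf[3], 0L)        # post at 100, arrivals 101+: none count
})

test_that("plasticity disabled leaves the latency series flat", {
  l <- run_latency_experiment(a_plus_frac = 0, duration_ms = 1000, seed = 1)
  expect_equal(unique(l$metrics$spikes_to_fire), 10L)
  expect_equal(l$metrics$w_final, rep(l$metrics$w0, 10))
})

test_that("song control with plasticity disabled keeps the weights", {
  s <- run_song_experiment(duration_ms = 2000, plastic = FALSE, seed = 1)
  expect_equal(s$metrics$w_final, s$metrics$w_initial)
  expect_equal(s$metrics$bimodality_final, s$metrics$bimodality_initial)
})

test_that("vg rule with all increments zero leaves behaviour unchanged", {
  lif <- lif_params(tau_m = 10, tau_syn = 1, t_refrac = 2)
  burst <- c(0, 2, 4)
  w0 <- calibrate_weight(lif, burst)
  prm <- vg_params(a = 0, b = 0, alpha = 0, beta = 0, theta_w = w0,
                   w_min = 0, w_max = 2 * w0)
  net <- single_synapse_net(as.vector(outer(burst, c(0, 200, 400), "+")),
                            w = w0, d = 1, lif = lif, plastic = TRUE,
                            rule = list(name = "vg_stdp", params = prm))
  rec <- run_network(net, 600, seed = 1)
  expect_equal(rec$weights[[1]], w0)
  stf <- spikes_to_fire(rec, c(0, 200, 400), 1, 2, delay = 1)
  expect_equal(unique(stf), 3L)
})

test_that("teacher experiments potentiate until the stimulus drives the target", {
  t <- run_teacher_experiment(seed = 1)
  expect_equal(t$metrics$target_spikes_phase1, 0L)
  expect_gt(t$metrics$target_spikes_test, 10)
  expect_gt(t$metrics$w_mean_final, t$metrics$w_mean_initial)

  b <- run_bcm_teacher_experiment(seed = 1)
  expect_equal(b$metrics$target_spikes_before, 0L)
  expect_gt(b$metrics$target_spikes_after, 10)
  expect_gt(b$metrics$w_mean_final, b$metrics$w_mean_initial)
})

test_that("run_experiment dispatches and rejects unknown names", {
  r <- run_experiment("burst_stdp", seed = 1)
  expect_s3_class(r, "experiment_result")
  expect_error(run_experiment("nope"), "unknown experiment")
})
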