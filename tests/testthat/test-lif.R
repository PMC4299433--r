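# LIF neuron: single-step contract and closed-form sub-threshold behaviour.

test_that("step_neuron honours equilibrium, threshold and refractory", {
  p <- lif_params()
  s <- neuron_state(p)
  # equilibrium: no input, v stays at rest
  for (t in 1:5) s <- step_neuron(s, p, 0, t)$state
  expect_equal(s$v, p$v_rest)

  # forced above threshold: spike, reset, refractory clamp
  s <- neuron_state(p, v = p$v_thresh + 5)
  r <- step_neuron(s, p, 0, t = 7)
  expect_true(r$spiked)
  expect_equal(r$state$v, p$v_reset)
  expect_equal(r$state$refrac_remaining, p$t_refrac)
  expect_equal(r$state$last_spike_time, 7)
  # held at reset while refractory counts down
  r2 <- step_neuron(r$state, p, input = 100)
  expect_false(r2$spiked)
  expect_equal(r2$state$v, p$v_reset)

  expect_error(step_neuron(s, p, Inf), "non-finite")
})

test_that("constant current relaxes to v_rest + r_m * I (closed form)", {
  p <- lif_params(i_offset = 5, r_m = 2, v_thresh = 0)  # stays subthreshold
  s <- neuron_state(p, v = p$v_rest)
  v <- numeric(400)
  for (t in seq_len(400)) {
    s <- step_neuron(s, p, 0, t)$state
    v[t] <- s$v
  }
  expect_equal(v[400], p$v_rest + p$r_m * p$i_offset, tolerance = 1e-8)
  # full trajectory matches the exponential relaxation closed form
  expect_equal(v, p$v_rest + p$r_m * p$i_offset * (1 - exp(-(1:400) / p$tau_m)),
               tolerance = 1e-10)
})

test_that("engine sub-threshold response equals the continuous closed form", {
  p <- lif_params()
  net <- single_synapse_net(c(20, 40), w = 2, d = 5, lif = p)
  rec <- run_network(net, 150, seed = 1, record_v = neuron_ids(net, "out"))
  v <- rec$v[, 1]
  # independent oracle: superposition of exact PSP kernels at t + d
  h <- function(t) ifelse(t < 0, 0, p$tau_syn / (p$tau_syn - p$tau_m) *
                            (exp(-t / p$tau_syn) - exp(-t / p$tau_m)))
  # discrete deliveries: current added at step start, so the kernel is
  # evaluated at integer lags from the arrival step
  closed <- sapply(seq_len(150) - 1, function(t)
    2 * p$r_m * sum(h(t - c(25, 45) + 1)))
  expect_equal(unname(v - p$v_rest), closed, tolerance = 1e-10)
  # delay correctness: deflection starts exactly at t + d
  expect_equal(which(abs(v - p$v_rest) > 1e-12)[1], 26)
})

test_that("calibrate_weight makes n spikes just cross and n-1 stay below", {
  p <- lif_params(tau_m = 10, tau_syn = 1)
  arr <- c(0, 2, 4)
  w0 <- calibrate_weight(p, arr)
  gap <- p$v_thresh - p$v_rest
  expect_gte(max(lif_deflection(p, arr)) * w0, gap)
  expect_lt(max(lif_deflection(p, arr[1:2])) * w0, gap)
})

test_that("sub-threshold responses superpose linearly", {
  p <- lif_params()
  d1 <- lif_deflection(p, 10, duration = 120)
  d2 <- lif_deflection(p, 30, duration = 120)
  d12 <- lif_deflection(p, c(10, 30), duration = 120)
  expect_equal(d12, d1 + d2, tolerance = 1e-12)
})
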