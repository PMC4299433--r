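# Engine-level contracts: spike delivery, run determinism, recording.

test_that("deliver_spike accumulates into slot t + d per entry", {
  b <- input_ring_buffer(4, span = 16)
  row <- synaptic_row(1, post = 3, w = 2, d = 5)
  b <- deliver_spike(row, b, t = 10)
  expect_equal(b$e[(15 %% 16) + 1, 3], 2)
  # linear superposition of two identical spikes
  b <- deliver_spike(row, b, t = 10)
  expect_equal(b$e[(15 %% 16) + 1, 3], 4)
  # empty row: no change
  b2 <- deliver_spike(synaptic_row(1, post = integer(0)), b, t = 10)
  expect_identical(b2, b)
  # delay exceeding the span is a configuration error
  expect_error(deliver_spike(synaptic_row(1, post = 1, d = 16), b, 0),
               "span")
  # inhibitory lane is kept separate
  b3 <- deliver_spike(synaptic_row(1, post = 2, w = -9, d = 1),
                      input_ring_buffer(4, 16), t = 0, lane = "inh")
  expect_equal(b3$i[2, 2], -9)
  expect_equal(sum(b3$e), 0)
})

test_that("consumed slots are zeroed after use", {
  b <- input_ring_buffer(2, span = 8)
  b <- deliver_spike(synaptic_row(1, post = 1, w = 3, d = 2), b, t = 0)
  r <- plastisim:::consume_inputs(b, 2)
  expect_equal(r$e, c(3, 0))
  expect_equal(plastisim:::consume_inputs(r$buffers, 2)$e, c(0, 0))
})

test_that("run is deterministic and duration 0 yields empty recordings", {
  pops <- list(
    population("src", 5, "source",
               stimulus = list(type = "poisson", rate = 50,
                               start = 0, stop = 500)),
    population("out", 2, "lif"))
  prj <- list(projection("src", "out", list(type = "all_to_all"),
                         weight = 1, delay = 2))
  net <- network(pops, prj, seed = 3)
  r0 <- run_network(net, 0, seed = 1)
  expect_equal(nrow(r0$spikes), 0)
  r1 <- run_network(net, 500, seed = 7)
  r2 <- run_network(net, 500, seed = 7)
  expect_identical(r1$spikes, r2$spikes)
  r3 <- run_network(net, 500, seed = 8)
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("Poisson source spike count is within 4 sd of its expectation", {
  pops <- list(population("p", 1, "source",
                          stimulus = list(type = "poisson", rate = 20,
                                          start = 0, stop = 60000)))
  net <- network(pops, list(), seed = 1)
  lam <- 20 * 60
  for (sd in 1:4) {
    n <- nrow(run_network(net, 60000, seed = sd)$spikes)
    expect_lt(abs(n - lam), 4 * sqrt(lam))
  }
})

test_that("every emitted spike is delivered to every row entry exactly once", {
  # two posts with different delays: each source spike must deflect both
  # membranes exactly once, at the correct lag
  pops <- list(
    population("s", 1, "source",
               stimulus = list(type = "schedule", times = list(c(10, 60)))),
    population("o", 2, "lif"))
  prj <- list(projection("s", "o",
                         data.frame(pre = c(1, 1), post = c(1, 2),
                                    w = c(1, 1), d = c(2, 9))))
  net <- network(pops, prj, seed = 1)
  rec <- run_network(net, 120, seed = 1, record_v = neuron_ids(net, "o"))
  p <- lif_params()
  for (j in 1:2) {
    d <- c(2, 9)[j]
    onsets <- which(abs(diff(rec$v[, j])) > 1e-12 &
                      abs(rec$v[-1, j] - p$v_rest) > 1e-12)
    expect_equal(onsets[1] + 1, 10 + d + 1)
  }
})
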