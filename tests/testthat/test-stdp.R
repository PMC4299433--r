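# Trace-based STDP: kernel shape and batched-pass equivalence with the
# brute-force all-pairs oracle.

test_that("stdp_F has the double-exponential form with depression at 0", {
  p <- stdp_params(a_plus = 1, a_minus = 0.8, tau_plus = 15, tau_minus = 30)
  expect_equal(stdp_F(-15, p), exp(-1))
  expect_equal(stdp_F(0, p), -0.8)          # dt >= 0 branch includes 0
  expect_equal(stdp_F(30, p), -0.8 * exp(-1))
  # sign pattern for any positive parameters
  expect_gt(stdp_F(-5, p), 0)
  expect_lt(stdp_F(5, p), 0)
})

test_that("empty windows leave weights unchanged", {
  prm <- stdp_params(a_plus = 0.5, a_minus = 0.5, w_min = -10, w_max = 10)
  expect_equal(run_stdp_windows(numeric(0), numeric(0), d = 3, prm,
                                n_win = 2, w0 = 1.5), 1.5)
})

test_that("batched pass equals the all-pairs oracle (random sets, delays)", {
  prm <- stdp_params(a_plus = 0.31, a_minus = 0.42, tau_plus = 17,
                     tau_minus = 23, w_min = -1e9, w_max = 1e9)
  set.seed(101)
  worst <- 0
  for (rep in 1:120) {
    d <- sample(1:40, 1)
    pre <- sort(sample(0:127, sample(0:10, 1)))
    post <- sort(sample(0:127, sample(0:10, 1)))
    got <- run_stdp_windows(pre, post, d, prm, n_win = 3)
    want <- stdp_allpairs_oracle(pre, post, d, prm)
    worst <- max(worst, abs(got - want) / max(1e-12, abs(want)))
  }
  expect_lt(worst, 1e-9)
})

test_that("ignoring the delay would give a different (wrong) update", {
  prm <- stdp_params(a_plus = 0.3, a_minus = 0.3, w_min = -1e9, w_max = 1e9)
  pre <- c(10, 40); post <- c(20, 55)
  w_d1 <- run_stdp_windows(pre, post, 1, prm, n_win = 2)
  w_d10 <- run_stdp_windows(pre, post, 10, prm, n_win = 2)
  expect_equal(w_d10, stdp_allpairs_oracle(pre, post, 10, prm),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(w_d1, w_d10)))
})

test_that("weights are clipped to the rule bounds after a pass", {
  prm <- stdp_params(a_plus = 5, a_minus = 0, w_min = 0, w_max = 1)
  w <- run_stdp_windows(pre = 10, post = 20, d = 1, prm, n_win = 1,
                        w0 = 0.9)
  expect_equal(w, 1)
  prm2 <- stdp_params(a_plus = 0, a_minus = 5, w_min = 0.2, w_max = 1)
  w2 <- run_stdp_windows(pre = 30, post = 20, d = 1, prm2, n_win = 1,
                         w0 = 0.4)
  expect_equal(w2, 0.2)
})
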