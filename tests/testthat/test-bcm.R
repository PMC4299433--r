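# BCM rule: pointwise form, sliding threshold, and convergence properties.

test_that("bcm_dw matches the rule pointwise", {
  p <- bcm_params(delta = 1e-4, epsilon = 0)
  expect_equal(bcm_dw(10, 50, 35, 0, p), 0.75)   # direct substitution
  expect_equal(bcm_dw(10, 35, 35, 2, p), 0)      # zero crossing at theta
  expect_equal(bcm_dw(0, 50, 35, 2, p), 0)       # gated by the pre rate
  p2 <- bcm_params(delta = 1e-4, epsilon = 0.2)
  expect_equal(bcm_dw(0, 0, 0, 3, p2, dt_s = 0.5), -0.2 * 3 * 0.5)
})

test_that("update_theta is the stated EMA", {
  expect_equal(update_theta(12, 40, 1), 40)      # ema = 1 copies the rate
  th <- 0
  for (r in c(0, 80)) th <- update_theta(th, r, 0.5)
  expect_equal(th, 40)  # hand iteration: 0.5*0 = 0, then 0.5*0 + 0.5*80
  # geometric convergence to a constant rate
  th <- 5
  for (k in 1:200) th <- update_theta(th, 30, 0.1)
  expect_equal(th, 30, tolerance = 1e-6)
})

test_that("weight converges to the closed-form fixed point under frozen theta", {
  p <- bcm_params(delta = 2e-5, epsilon = 0.01)
  r_pre <- 10; r_post <- 50; theta <- 35
  w_star <- p$delta * r_post * (r_post - theta) * r_pre / p$epsilon
  w <- 0
  for (k in 1:8000) w <- w + bcm_dw(r_pre, r_post, theta, w, p,
                                    dt_s = 0.128)
  expect_equal(w, w_star, tolerance = 0.01)
})

test_that("the batched BCM pass slides theta to a stationary post rate", {
  # one pre at ~39 Hz (5 spikes/window), one post at ~23 Hz (3/window)
  prm <- bcm_params(delta = 0, epsilon = 1e-12, theta_ema = 0.1,
                    rate_lp = 0.5, w_min = 0, w_max = 1)
  proj <- list(plastic = TRUE, pre = 1L, post = 2L, d = 1L, w = 0.5,
               n_pre = 1L, src_offset = 0L,
               rule = list(name = "bcm", params = prm))
  post_rate <- 3 / 0.128
  for (k in 0:400) {
    t0 <- k * 128
    proj <- run_plasticity_pass(
      proj, c(t0, t0 + 128),
      list(id = rep(1L, 5), time = t0 + c(10, 35, 60, 85, 110)),
      list(id = rep(2L, 3), time = t0 + c(20, 60, 100)))
  }
  expect_equal(proj$pstate$theta, post_rate, tolerance = 1e-3)
  expect_equal(proj$pstate$r_post, post_rate, tolerance = 1e-3)
})
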