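# Voltage-gated bistable STDP: jump conditions, drift dynamics, bounds.

vg_row_once <- function(w0, d, pre_t, post_t, vbits, prm, state = NULL,
                        t0 = 0) {
  row <- synaptic_row(1, post = 2, w = w0, d = d)
  pw <- spike_window(t0)
  for (t in pre_t) pw <- record_pre_spike(pw, t)
  res <- vg_update_row(row, pw, list(`2` = vbits), list(`2` = post_t),
                       prm, state)
  res
}

test_that("jump conditions follow the membrane and calcium gates", {
  base <- vg_params(j_c = 1, tau_c = 1e9, theta_v = -55,
                    theta_h_down = 0.5, theta_h_up = 2,
                    theta_l_down = 0.5, theta_l_up = 2,
                    a = 0.1, b = 0.04, alpha = 0, beta = 0,
                    theta_w = 0.5, w_min = 0, w_max = 1)
  up <- rep(TRUE, 128); down <- rep(FALSE, 128)
  # pre spike at bin centre 11 (+d 1 -> arrival 12), post spike at 2 puts
  # calcium at ~j_c inside both eligibility intervals
  r1 <- vg_row_once(0.3, 1, 11, 2, up, base)
  expect_equal(r1$row$w, 0.4)                       # V high -> +a
  r2 <- vg_row_once(0.3, 1, 11, 2, down, base)
  expect_equal(r2$row$w, 0.3 - 0.04)                # V low -> -b
  # calcium outside the interval: no jump either way
  none <- vg_params(j_c = 0.1, tau_c = 1e9, theta_v = -55,
                    theta_h_down = 0.5, theta_h_up = 2,
                    theta_l_down = 0.5, theta_l_up = 2,
                    a = 0.1, b = 0.04, alpha = 0, beta = 0,
                    theta_w = 0.5, w_min = 0, w_max = 1)
  expect_equal(vg_row_once(0.3, 1, 11, 2, up, none)$row$w, 0.3)
  # no pre spikes at all: weight only drifts (zero drift here)
  expect_equal(vg_row_once(0.3, 1, numeric(0), 2, up, base)$row$w, 0.3)
})

test_that("missing membrane bitmap is a configuration error", {
  prm <- vg_params()
  expect_error(
    plastisim:::vg_pass(prm, plastisim:::make_vg_state(1L, 2L, 1L), 0.3,
                        0, 128, list(id = 1L, time = 11),
                        list(idx = integer(0), time = numeric(0),
                             count = integer(0)), NULL),
    "configuration error")
})

test_that("drift is bistable with analytically predicted crossing times", {
  prm <- vg_params(a = 0, b = 0, alpha = 1e-3, beta = 2e-3,
                   theta_w = 0.5, w_min = 0, w_max = 1)
  vb <- rep(FALSE, 128)
  # above theta_w: climbs by alpha per ms, saturating at w_max
  w <- 0.6; st <- NULL
  n_up <- ceiling((1 - 0.6) / (1e-3 * 128))  # predicted passes to reach top
  traj <- numeric(0)
  for (k in 1:(n_up + 1)) {
    r <- vg_row_once(w, 1, numeric(0), numeric(0), vb, prm, st,
                     t0 = (k - 1) * 128)
    w <- r$row$w; st <- r$state; traj <- c(traj, w)
  }
  expect_equal(w, 1)
  expect_lt(traj[n_up - 1], 1)      # not earlier than predicted
  expect_true(all(diff(traj) >= 0)) # monotone
  # at or below theta_w: decays by beta per ms (boundary uses down branch)
  w <- 0.5; st <- NULL
  n_dn <- ceiling(0.5 / (2e-3 * 128))
  for (k in 1:(n_dn + 1)) {
    r <- vg_row_once(w, 1, numeric(0), numeric(0), vb, prm, st,
                     t0 = (k - 1) * 128)
    w <- r$row$w; st <- r$state
  }
  expect_equal(w, 0)
})

test_that("weights stay inside [w_min, w_max] under any pass", {
  set.seed(5)
  prm <- vg_params(j_c = 1, tau_c = 30, theta_v = -55,
                   theta_h_down = 0.1, theta_h_up = 2,
                   theta_l_down = 0.1, theta_l_up = 2,
                   a = 0.4, b = 0.4, alpha = 5e-3, beta = 5e-3,
                   theta_w = 0.5, w_min = 0.1, w_max = 0.9)
  for (rep in 1:10) {
    w <- runif(1)
    st <- NULL
    for (k in 0:2) {
      r <- vg_row_once(w, sample(1:5, 1),
                       sort(sample(seq(0, 126, 2), 4)) + k * 128,
                       sort(sample(0:127, 3)) + k * 128,
                       sample(c(TRUE, FALSE), 128, replace = TRUE),
                       prm, st, t0 = k * 128)
      w <- r$row$w; st <- r$state
      expect_gte(w, 0.1); expect_lte(w, 0.9)
    }
  }
})
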