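# Stimulus generators: purity, statistics and geometry.

test_that("poisson_train is pure, seeded and statistically calibrated", {
  expect_equal(poisson_train(0, 0, 1000, 3, seed = 1),
               list(numeric(0), numeric(0), numeric(0)))
  a <- poisson_train(20, 0, 300000, seed = 4)
  b <- poisson_train(20, 0, 300000, seed = 4)
  expect_identical(a, b)
  lam <- 20 * 300
  expect_lt(abs(length(a[[1]]) - lam), 4 * sqrt(lam))
  expect_warning(poisson_train(1500, 0, 100), "capping")
  # spike times are integer ms within [start, stop)
  tr <- poisson_train(100, 50, 250, seed = 2)[[1]]
  expect_true(all(tr >= 50 & tr < 250))
  expect_true(all(tr == floor(tr)))
})

test_that("teacher_protocol shifts target bursts by the configured lag", {
  tp <- teacher_protocol(c(100, 500), target_lag = 10, seed = 3)
  expect_equal(tp$target_onsets, c(110, 510))
  # target spikes fall inside the lag-shifted burst windows
  expect_true(all((tp$target[[1]] >= 110 & tp$target[[1]] < 130) |
                    (tp$target[[1]] >= 510 & tp$target[[1]] < 530)))
  # lag 0: coincident windows
  tp0 <- teacher_protocol(100, 0, seed = 3)
  expect_equal(tp0$stimulus_onsets, tp0$target_onsets)
  # empty schedule propagates
  tpe <- teacher_protocol(numeric(0), 10, seed = 3)
  expect_length(tpe$stimulus[[1]], 0)
})

test_that("bar images have the stated geometry and intensity range", {
  angles <- c(0, 45, 90, 135)
  imgs <- lapply(angles, bar_image, seed = 1)
  on_counts <- vapply(imgs, function(b) sum(b$image > 0), numeric(1))
  expect_true(all(on_counts >= 30 & on_counts <= 46))  # ~ 3 x 12, rounding
  vals <- unlist(lapply(imgs, function(b) b$image[b$image > 0]))
  expect_true(all(vals >= 0.8 & vals <= 1.0))
  # pairwise distinct pixel sets at the four training angles
  sets <- lapply(imgs, function(b) which(b$image > 0))
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(setequal(sets[[i]], sets[[j]]))
  # 180-degree rotation keeps the on-pixel set
  expect_equal(which(bar_image(30, seed = 1)$image > 0),
               which(bar_image(210, seed = 1)$image > 0))
})

test_that("bar_rates scales intensities to the requested total", {
  b <- bar_image(45, seed = 2)
  r <- bar_rates(b, total_rate = 1000)
  expect_equal(sum(r), 1000)
  expect_equal(bar_rates(matrix(0, 4, 4), 1000), matrix(0, 4, 4))
})

test_that("sweep_spikes produces the stated orders", {
  fw <- sweep_spikes("forward", 4, inter_channel_dt = 10)
  expect_equal(unlist(fw), c(0, 10, 20, 30))
  bw <- sweep_spikes("backward", 4, inter_channel_dt = 10)
  expect_equal(unlist(bw), rev(unlist(fw)))
  fk <- sweep_spikes("forked", 5, inter_channel_dt = 10)
  expect_equal(unlist(fk), c(20, 10, 0, 10, 20))  # middle first, mirror out
  # repeats advance by span + gap
  fw2 <- sweep_spikes("forward", 3, 10, repeat_gap = 50, n_repeats = 2)
  expect_equal(fw2[[1]], c(0, 70))
  expect_error(sweep_spikes("forward", 2), "n_channels")
})
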