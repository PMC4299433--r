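# Spike windows, double buffering and the bitmap quantization.

test_that("record_pre_spike sets the floor bin and collapses same-bin spikes", {
  w <- spike_window(phase_start = 128)
  w <- record_pre_spike(w, 130)
  expect_equal(which(w$bits), 2L)  # floor((130 - 128) / 2) = bin index 1

  w0 <- spike_window(0)
  w0 <- record_pre_spike(w0, 10.0)
  w0 <- record_pre_spike(w0, 11.0)
  expect_equal(which(w0$bits), 6L)  # both in bin 5 (0-based), one set bit

  # half-open window: t = 127 belongs to window 0, t = 128 does not
  w1 <- spike_window(0)
  w1 <- record_pre_spike(w1, 127)
  expect_equal(which(w1$bits), 64L)
  expect_error(record_pre_spike(w1, 128), "outside")
  w2 <- record_pre_spike(spike_window(128), 128)
  expect_equal(which(w2$bits), 1L)
})

test_that("swap_and_clear preserves the readable window and isolates new spikes", {
  b <- double_buffer(0)
  b <- record_into_buffer(b, 10)
  b <- record_into_buffer(b, 100)
  b <- swap_and_clear(b, 128)
  old <- readable_window(b)
  expect_equal(which(old$bits), c(6L, 51L))
  expect_equal(old$phase_start, 0)
  # spikes after the swap land only in the new active window
  b <- record_into_buffer(b, 130)
  expect_equal(which(readable_window(b)$bits), c(6L, 51L))
  expect_equal(which(b$windows[[b$active_parity + 1L]]$bits), 2L)
  # two swaps restore the original parity
  b2 <- swap_and_clear(swap_and_clear(double_buffer(0), 128), 256)
  expect_equal(b2$active_parity, 0L)
  expect_error(swap_and_clear(b, 100), "multiple")
})

test_that("no spike is lost across windows (bitmap occupancy property)", {
  set.seed(7)
  for (rep in 1:20) {
    spikes <- sort(sample(0:511, sample(5:60, 1)))
    b <- double_buffer(0)
    got <- list()
    for (k in 0:3) {
      for (t in spikes[spikes >= k * 128 & spikes < (k + 1) * 128])
        b <- record_into_buffer(b, t)
      b <- swap_and_clear(b, (k + 1) * 128)
      w <- readable_window(b)
      got[[k + 1]] <- w$phase_start + (which(w$bits) - 1) * w$bin_ms
    }
    expect_equal(sort(unlist(got)), sort(unique(2 * floor(spikes / 2))))
  }
})

test_that("vectorised quantization matches per-spike window recording", {
  set.seed(11)
  for (rep in 1:10) {
    times <- sort(sample(0:127, sample(1:40, 1), replace = TRUE))
    w <- spike_window(0)
    for (t in times) w <- record_pre_spike(w, t)
    q <- plastisim:::quantize_spikes(times, rep(1L, length(times)), 0, 2)
    expect_equal(sort(q$time), (which(w$bits) - 1) * 2 + 1)
  }
})
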