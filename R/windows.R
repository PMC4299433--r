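# Spike-history windows: fixed-span bitmaps at coarse resolution, plus the
# double-buffer bookkeeping that separates the window being recorded from
# the window being consumed by the batched plasticity pass.
#
# Windows are half-open [phase_start, phase_start + window_ms): a spike
# exactly at a boundary belongs to the new window.  A bit is set iff at
# least one spike fell into that bin (same-bin spikes collapse).

#' Create an empty spike-history window
#'
#' @param phase_start start of the window (ms)
#' @param window_ms window span (ms), default 128
#' @param bin_ms bin width (ms), default 2; must divide `window_ms`
#' @return a `spike_window` object with a logical `bits` vector of
#'   `window_ms / bin_ms` bins
#' @export
spike_window <- function(phase_start = 0, window_ms = 128, bin_ms = 2) {
  stopifnot(window_ms > 0, bin_ms > 0, window_ms %% bin_ms == 0)
  structure(list(bits = logical(window_ms / bin_ms),
                 phase_start = phase_start, window_ms = window_ms,
                 bin_ms = bin_ms),
            class = "spike_window")
}

#' Record a presynaptic spike into the active window bitmap
#'
#' Sets bit `floor((t - phase_start) / bin_ms)`.  Recording is idempotent
#' for spikes falling into the same bin.  A time outside the half-open
#' window is a hard failure, since it indicates a buffering bug.
#'
#' @param window a [spike_window()] object
#' @param t spike time (ms)
#' @return the updated window
#' @examples
#' w <- spike_window(phase_start = 128)
#' which(record_pre_spike(w, 130)$bits)  # bin 2 (1-based), i.e. bin index 1
#' @export
record_pre_spike <- function(window, t) {
  if (t < window$phase_start || t >= window$phase_start + window$window_ms)
    stop(sprintf(
      "spike at t = %s ms outside active window [%s, %s): buffering bug",
      t, window$phase_start, window$phase_start + window$window_ms))
  bin <- floor((t - window$phase_start) / window$bin_ms) + 1L
  window$bits[bin] <- TRUE
  window
}

#' Create a double-buffered pair of spike windows
#'
#' Two alternating windows per tracked neuron: the active parity receives
#' current spikes while the other parity holds the completed previous
#' window for the plasticity pass.  The pass must only ever read the
#' non-active parity.
#'
#' @param phase_start start of the first (active) window (ms)
#' @inheritParams spike_window
#' @return a `double_buffer` object with fields `windows` (list of two
#'   [spike_window()]s) and `active_parity` (0 or 1)
#' @export
double_buffer <- function(phase_start = 0, window_ms = 128, bin_ms = 2) {
  structure(list(
    windows = list(spike_window(phase_start, window_ms, bin_ms),
                   spike_window(phase_start - window_ms, window_ms, bin_ms)),
    active_parity = 0L), class = "double_buffer")
}

#' Swap the double buffer at a window boundary
#'
#' Flips the active parity, clears the newly active window and re-anchors it
#' at `boundary_t`.  The previously active window is left untouched so the
#' plasticity pass can read it.
#'
#' @param buffer a [double_buffer()] object
#' @param boundary_t the boundary time (ms); must be a multiple of the
#'   window span
#' @return the updated buffer
#' @export
swap_and_clear <- function(buffer, boundary_t) {
  w <- buffer$windows[[1]]
  if (boundary_t %% w$window_ms != 0)
    stop("boundary_t must be a multiple of the window span")
  new_active <- 1L - buffer$active_parity
  buffer$windows[[new_active + 1L]] <-
    spike_window(boundary_t, w$window_ms, w$bin_ms)
  buffer$active_parity <- new_active
  buffer
}

#' Record a spike into the active window of a double buffer
#'
#' @param buffer a [double_buffer()] object
#' @param t spike time (ms)
#' @return the updated buffer
#' @export
record_into_buffer <- function(buffer, t) {
  i <- buffer$active_parity + 1L
  buffer$windows[[i]] <- record_pre_spike(buffer$windows[[i]], t)
  buffer
}

#' Read the completed (non-active) window of a double buffer
#'
#' @param buffer a [double_buffer()] object
#' @return the [spike_window()] holding the previous phase
#' @export
readable_window <- function(buffer) {
  buffer$windows[[2L - buffer$active_parity]]
}

# Vectorised equivalent of filling a window bitmap spike by spike: quantize
# (id, time) pairs within [t0, t0 + window_ms) to unique (id, bin-centre)
# pairs.  Semantically identical to record_pre_spike() per spike (asserted
# by tests); used on the hot path where per-spike R calls would be too slow.
quantize_spikes <- function(times, ids, t0, bin_ms = 2) {
  if (length(times) == 0)
    return(list(id = integer(0), time = numeric(0)))
  bin <- floor((times - t0) / bin_ms)
  key <- as.numeric(ids) * 2^20 + bin  # exact for < 2^33 ids, 2^20 bins
  keep <- !duplicated(key)
  centre <- t0 + bin[keep] * bin_ms + bin_ms / 2
  o <- order(centre, ids[keep])
  list(id = ids[keep][o], time = centre[o])
}

# Bitmap matrix (n_bins x n_ids) from spike lists, window [t0, t0 + span).
window_bitmap <- function(times, ids, t0, span, bin_ms, n_ids) {
  nb <- ceiling(span / bin_ms)
  m <- matrix(FALSE, nb, n_ids)
  if (length(times)) {
    bin <- floor((times - t0) / bin_ms) + 1L
    ok <- bin >= 1L & bin <= nb
    m[cbind(bin[ok], ids[ok])] <- TRUE
  }
  m
}
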