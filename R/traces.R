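# Exponentially decaying per-neuron traces.  Between spikes a trace obeys
# dx/dt = -x / tau; at each spike it jumps by A.  The update is the exact
# solution, so advancing over any partition of an interval equals the
# single-interval update (semigroup property), and the value carries over
# from one plasticity window to the next.

#' Create a spike trace
#'
#' @param tau decay time constant (ms)
#' @param a increment per spike
#' @param x initial value
#' @param t time the value refers to (ms)
#' @return a `trace_state` object
#' @export
trace_state <- function(tau, a = 1, x = 0, t = 0) {
  stopifnot(tau > 0, x >= 0)
  structure(list(x = x, tau = tau, a = a, last_update_t = t),
            class = "trace_state")
}

# exact decay + per-spike bumps; spike times must be non-decreasing and in
# [from, to]; returns value at `to`
advance_trace <- function(x, tau, a, from, spikes, to) {
  if (length(spikes)) {
    if (is.unsorted(spikes)) stop("spike times must be chronological")
    if (spikes[1] < from || spikes[length(spikes)] > to)
      stop("spike times outside the update interval")
    for (s in spikes) {
      x <- x * exp(-(s - from) / tau) + a
      from <- s
    }
  }
  x * exp(-(to - from) / tau)
}

#' Advance a spike trace to a later time
#'
#' Applies the exact solution of the trace dynamics: exponential decay
#' between spikes and a jump of `a` at each spike time.  Spike times must be
#' chronological and lie in `(last_update_t, now]`; unordered input is a
#' hard failure.
#'
#' @param trace a [trace_state()] object
#' @param spike_times spike times (ms), chronological
#' @param now target time (ms), `>= last_update_t`
#' @return the updated trace, valued at `now`
#' @examples
#' tr <- trace_state(tau = 20, x = 1)
#' update_trace(tr, numeric(0), now = 20)$x  # exp(-1)
#' @export
update_trace <- function(trace, spike_times, now) {
  stopifnot(now >= trace$last_update_t)
  trace$x <- advance_trace(trace$x, trace$tau, trace$a,
                           trace$last_update_t, spike_times, now)
  trace$last_update_t <- now
  trace
}

#' Create a postsynaptic calcium trace
#'
#' The calcium variable jumps by `j_c` at every postsynaptic spike
#' (coincident spikes add their increments) and decays with `tau_c`; it
#' gates the eligibility intervals of the voltage-gated rule.
#'
#' @param params a [vg_params()] object (fields `j_c`, `tau_c`)
#' @param c0 initial concentration
#' @param t time the value refers to (ms)
#' @return a `calcium_trace` object
#' @export
calcium_trace <- function(params, c0 = 0, t = 0) {
  structure(list(c = c0, last_update_t = t,
                 j_c = params$j_c, tau_c = params$tau_c),
            class = "calcium_trace")
}

#' Advance a calcium trace over postsynaptic spikes
#'
#' @param ct a [calcium_trace()] object
#' @param post_spike_times postsynaptic spike times (ms), non-decreasing;
#'   `k` coincident spikes add `k * j_c`
#' @param now target time (ms)
#' @param params optional [vg_params()] overriding `j_c` and `tau_c`
#' @return the updated trace, valued at `now`
#' @export
calcium_step <- function(ct, post_spike_times, now, params = NULL) {
  if (!is.null(params)) {
    ct$j_c <- params$j_c
    ct$tau_c <- params$tau_c
  }
  stopifnot(now >= ct$last_update_t)
  ct$c <- advance_trace(ct$c, ct$tau_c, ct$j_c,
                        ct$last_update_t, post_spike_times, now)
  ct$last_update_t <- now
  ct
}
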