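# LIF propagators and closed-form helpers.
#
# The 1 ms update is the exact solution of the membrane equation
#   tau_m dv/dt = -(v - v_rest) + r_m (i_syn(t) + i_offset)
# with i_syn(t) = I0 exp(-t / tau_syn) over the step, so sub-threshold
# behaviour is free of integration error at any step size.

lif_propagators <- function(p) {
  em <- exp(-1 / p$tau_m)
  es <- exp(-1 / p$tau_syn)
  c_syn <- if (abs(p$tau_syn - p$tau_m) > 1e-12) {
    p$r_m * p$tau_syn / (p$tau_syn - p$tau_m) * (es - em)
  } else {
    p$r_m * (1 / p$tau_m) * em
  }
  list(em = em, es = es, c_syn = c_syn,
       c_off = p$r_m * p$i_offset * (1 - em))
}

#' Create a fresh LIF neuron state
#'
#' @param params a [lif_params()] object
#' @param v initial membrane potential (mV); defaults to the steady state
#'   `v_rest + r_m * i_offset`
#' @return a `neuron_state` list with fields `v`, `i_syn_e`, `i_syn_i`,
#'   `refrac_remaining` and `last_spike_time`
#' @export
neuron_state <- function(params,
                         v = params$v_rest + params$r_m * params$i_offset) {
  structure(list(v = v, i_syn_e = 0, i_syn_i = 0,
                 refrac_remaining = 0L, last_spike_time = NA_real_),
            class = "neuron_state")
}

#' Advance one LIF neuron by one 1 ms step
#'
#' Reference implementation of the per-step neuron update used by the
#' simulation kernel: the freshly delivered input is added to the synaptic
#' current, the membrane is propagated exactly over 1 ms, and a spike is
#' emitted if the potential reaches threshold at the end of the step (reset
#' plus refractory clamp follow).  The compiled engine performs the identical
#' computation; this function is the single-neuron contract used in tests
#' and for closed-form calibration.
#'
#' @param state a [neuron_state()] object
#' @param params a [lif_params()] object
#' @param input accumulated synaptic weight arriving this millisecond (nA);
#'   either a single signed number (excitatory lane) or a length-2 vector
#'   `c(exc, inh)`
#' @param t current time (ms), only used to stamp `last_spike_time`
#' @return `list(state = <updated state>, spiked = <logical>)`
#' @examples
#' p <- lif_params()
#' s <- neuron_state(p)
#' step_neuron(s, p, input = 0)$spiked
#' @export
step_neuron <- function(state, params, input = 0, t = 0) {
  if (length(input) == 1) input <- c(input, 0)
  if (!all(is.finite(input)) || !is.finite(state$v))
    stop(sprintf("non-finite state for neuron at t = %s ms", t))
  pr <- lif_propagators(params)
  i0e <- state$i_syn_e + input[1]
  i0i <- state$i_syn_i + input[2]
  i0 <- i0e + i0i
  spiked <- FALSE
  if (state$refrac_remaining > 0) {
    state$refrac_remaining <- state$refrac_remaining - 1L
    state$v <- params$v_reset
  } else {
    state$v <- params$v_rest + (state$v - params$v_rest) * pr$em +
      pr$c_off + i0 * pr$c_syn
    if (!is.finite(state$v))
      stop(sprintf("non-finite state for neuron at t = %s ms", t))
    if (state$v >= params$v_thresh) {
      spiked <- TRUE
      state$v <- params$v_reset
      state$refrac_remaining <- params$t_refrac
      state$last_spike_time <- t
    }
  }
  state$i_syn_e <- i0e * pr$es
  state$i_syn_i <- i0i * pr$es
  list(state = state, spiked = spiked)
}

#' Sub-threshold membrane deflection for a spike arrival pattern
#'
#' Computes, with the threshold disabled, the membrane deflection (mV above
#' the steady-state baseline `v_rest + r_m * i_offset`) at the end of every
#' millisecond step for unit-weight spikes arriving at `arrivals`.  Because
#' the response is linear in the synaptic weight, scaling by `w` gives the
#' exact trajectory for weight `w`; this is the closed form used to
#' calibrate "n spikes just reach threshold" initial weights.
#'
#' @param params a [lif_params()] object
#' @param arrivals integer arrival times (ms, step at which the weight is
#'   delivered), non-negative
#' @param duration number of steps to simulate; defaults to covering the
#'   arrivals plus five membrane time constants
#' @return numeric vector of deflections, element `t` giving the deflection
#'   at the end of step `t - 1` (time origin 0)
#' @export
lif_deflection <- function(params, arrivals, duration = NULL) {
  stopifnot(all(arrivals >= 0))
  if (is.null(duration))
    duration <- max(arrivals) + ceiling(5 * params$tau_m) + 1
  pr <- lif_propagators(params)
  inp <- numeric(duration)
  for (a in arrivals) inp[a + 1] <- inp[a + 1] + 1
  v <- numeric(duration)
  cur <- 0; dv <- 0
  for (k in seq_len(duration)) {
    cur <- cur + inp[k]
    dv <- dv * pr$em + cur * pr$c_syn
    v[k] <- dv
    cur <- cur * pr$es
  }
  v
}

#' Calibrate a synaptic weight so a spike pattern just reaches threshold
#'
#' Returns the weight `w0` such that the peak of the discrete-time membrane
#' response to unit spikes at `arrivals`, scaled by `w0`, equals
#' `margin * (v_thresh - v_rest - r_m * i_offset)`.  With the default
#' margin slightly above 1, the full pattern crosses threshold while any
#' strict prefix of it stays below (provided the prefix peak is smaller by
#' more than the margin, which holds for the burst fixtures used here).
#'
#' @inheritParams lif_deflection
#' @param margin multiplicative safety margin above exact tangency
#' @return the calibrated weight (nA)
#' @export
calibrate_weight <- function(params, arrivals, margin = 1.001) {
  gap <- params$v_thresh - (params$v_rest + params$r_m * params$i_offset)
  stopifnot(gap > 0)
  peak <- max(lif_deflection(params, arrivals))
  margin * gap / peak
}
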