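#' Leaky integrate-and-fire neuron parameters
#'
#' Constructs and validates the parameter set of the current-based LIF model
#' used by the simulation kernel.  The membrane integrates an exponentially
#' decaying synaptic current: each presynaptic spike adds its weight (nA) to
#' the current, which decays with `tau_syn`; the membrane potential relaxes
#' toward `v_rest + r_m * i_offset` with time constant `tau_m` and fires when
#' it reaches `v_thresh`, after which it is reset to `v_reset` and clamped
#' there for `t_refrac` ms.
#'
#' @param v_rest resting potential (mV)
#' @param v_reset reset potential (mV); must be below `v_thresh`
#' @param v_thresh firing threshold (mV)
#' @param tau_m membrane time constant (ms), > 0
#' @param tau_syn synaptic current decay time constant (ms), > 0
#' @param r_m membrane resistance (MOhm); converts nA to mV
#' @param t_refrac absolute refractory period (ms), >= 0, integer
#' @param i_offset constant bias current (nA)
#' @return an object of class `lif_params`
#' @examples
#' p <- lif_params()
#' p$tau_m
#' @export
lif_params <- function(v_rest = -65, v_reset = -65, v_thresh = -50,
                       tau_m = 20, tau_syn = 5, r_m = 1,
                       t_refrac = 2, i_offset = 0) {
  stopifnot(is.numeric(tau_m), tau_m > 0, is.numeric(tau_syn), tau_syn > 0,
            v_thresh > v_reset, t_refrac >= 0, r_m > 0)
  structure(list(v_rest = v_rest, v_reset = v_reset, v_thresh = v_thresh,
                 tau_m = tau_m, tau_syn = tau_syn, r_m = r_m,
                 t_refrac = as.integer(round(t_refrac)),
                 i_offset = i_offset),
            class = "lif_params")
}

#' Trace-based STDP parameters
#'
#' Parameters of the pair-based STDP kernel
#' \deqn{F(\Delta t) = A_+ e^{\Delta t/\tau_+} \;(\Delta t < 0), \qquad
#'       F(\Delta t) = -A_- e^{-\Delta t/\tau_-} \;(\Delta t \ge 0),}
#' with \eqn{\Delta t = t_{pre} - t_{post}} measured after synaptic delays
#' have been reintroduced at the postsynaptic end.  All spike pairs
#' contribute (all-to-all pairing via exponential traces).
#'
#' @param a_plus potentiation amplitude (weight units per pair)
#' @param a_minus depression amplitude (weight units per pair)
#' @param tau_plus potentiation time constant (ms)
#' @param tau_minus depression time constant (ms)
#' @param w_min,w_max hard weight bounds applied after each batched pass
#' @return an object of class `stdp_params`
#' @export
stdp_params <- function(a_plus = 0.1, a_minus = 0.1,
                        tau_plus = 20, tau_minus = 20,
                        w_min = 0, w_max = 1) {
  stopifnot(a_plus >= 0, a_minus >= 0, tau_plus > 0, tau_minus > 0,
            w_min <= w_max)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, w_min = w_min, w_max = w_max),
            class = "stdp_params")
}

#' BCM rule parameters
#'
#' Parameters of the rate-based BCM rule
#' \deqn{dw/dt = [r_{post}(r_{post} - \theta) r_{pre}]\,\delta - \epsilon w,}
#' applied once per plasticity window.  The modification threshold
#' \eqn{\theta} tracks the mean postsynaptic rate through an exponential
#' moving average with coefficient `theta_ema` per window; the pre- and
#' postsynaptic rates entering the product are single-pole low-pass filtered
#' window rates with coefficient `rate_lp`.
#'
#' @param delta learning rate (weight units per Hz^3 per second)
#' @param epsilon weight decay rate (per second)
#' @param theta_ema EMA coefficient for the threshold update, in (0, 1]
#' @param rate_lp low-pass coefficient for the filtered rates, in (0, 1]
#' @param theta0 initial modification threshold (Hz); `NA` starts the
#'   threshold at the first window's measured rate, a positive value
#'   equilibrates the rule (no initial blanket potentiation while the
#'   moving average warms up)
#' @param w_min,w_max hard weight bounds
#' @return an object of class `bcm_params`
#' @export
bcm_params <- function(delta = 1e-4, epsilon = 0, theta_ema = 0.1,
                       rate_lp = 0.5, theta0 = NA_real_,
                       w_min = 0, w_max = 1) {
  stopifnot(theta_ema > 0, theta_ema <= 1, rate_lp > 0, rate_lp <= 1,
            epsilon >= 0, w_min <= w_max)
  structure(list(delta = delta, epsilon = epsilon, theta_ema = theta_ema,
                 rate_lp = rate_lp, theta0 = theta0,
                 w_min = w_min, w_max = w_max),
            class = "bcm_params")
}

#' Voltage-gated bistable STDP parameters
#'
#' Parameters of the presynaptically triggered, voltage- and calcium-gated
#' rule.  At each presynaptic spike arrival the weight jumps by `+a` if the
#' postsynaptic membrane is above `theta_v` and the calcium trace lies in
#' `[theta_h_down, theta_h_up)`, or by `-b` if the membrane is at or below
#' `theta_v` and the calcium trace lies in `[theta_l_down, theta_l_up)`.
#' Between qualifying events the weight drifts at rate `alpha` toward
#' `w_max` when above `theta_w`, or at rate `-beta` toward `w_min` when at
#' or below it, making the synapse bistable.
#'
#' @param j_c calcium increment per postsynaptic spike
#' @param tau_c calcium decay time constant (ms)
#' @param theta_v membrane gating threshold (mV)
#' @param theta_h_down,theta_h_up calcium interval for potentiation
#' @param theta_l_down,theta_l_up calcium interval for depression
#' @param a potentiation jump (weight units)
#' @param b depression jump (weight units)
#' @param alpha upward drift rate (weight units per ms)
#' @param beta downward drift rate (weight units per ms)
#' @param theta_w drift threshold (weight units), within `[w_min, w_max]`
#' @param w_min,w_max stable weight bounds
#' @return an object of class `vg_params`
#' @export
vg_params <- function(j_c = 1, tau_c = 60, theta_v = -55,
                      theta_h_down = 0.1, theta_h_up = 2,
                      theta_l_down = 0.1, theta_l_up = 2,
                      a = 0.1, b = 0.1, alpha = 0, beta = 0,
                      theta_w = 0.5, w_min = 0, w_max = 1) {
  stopifnot(theta_h_down <= theta_h_up, theta_l_down <= theta_l_up,
            a >= 0, b >= 0, alpha >= 0, beta >= 0, tau_c > 0, j_c >= 0,
            w_min <= theta_w, theta_w <= w_max)
  structure(list(j_c = j_c, tau_c = tau_c, theta_v = theta_v,
                 theta_h_down = theta_h_down, theta_h_up = theta_h_up,
                 theta_l_down = theta_l_down, theta_l_up = theta_l_up,
                 a = a, b = b, alpha = alpha, beta = beta,
                 theta_w = theta_w, w_min = w_min, w_max = w_max),
            class = "vg_params")
}
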