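# Rate-based BCM rule on the batched schedule.  Each plasticity window
# supplies a presynaptic spike count per row (read from the 2 ms window
# bitmap) and an exact postsynaptic spike count; both are converted to Hz,
# low-pass filtered, and fed through the BCM nonlinearity.  The modification
# threshold theta slides as an exponential moving average of the measured
# postsynaptic window rate, so sustained activity above the neuron's own
# mean potentiates and activity below it depresses.

#' BCM weight change for one plasticity window
#'
#' Evaluates `dw = [r_post (r_post - theta) r_pre] delta dt - epsilon w dt`.
#'
#' @param r_pre presynaptic rate (Hz)
#' @param r_post postsynaptic rate (Hz)
#' @param theta modification threshold (Hz)
#' @param w current weight
#' @param params a [bcm_params()] object
#' @param dt_s window length in seconds (default 1 for a per-unit-time
#'   change)
#' @return the weight change for the window (not yet clipped)
#' @examples
#' bcm_dw(10, 50, 35, 0, bcm_params(delta = 1e-4, epsilon = 0))  # 0.75
#' @export
bcm_dw <- function(r_pre, r_post, theta, w, params, dt_s = 1) {
  stopifnot(all(r_pre >= 0), all(r_post >= 0))
  (r_post * (r_post - theta) * r_pre) * params$delta * dt_s -
    params$epsilon * w * dt_s
}

#' Slide the BCM modification threshold
#'
#' Exponential moving average toward the latest measured postsynaptic
#' window rate: `theta <- (1 - theta_ema) theta + theta_ema r_post_window`.
#'
#' @param theta current threshold (Hz)
#' @param r_post_window postsynaptic rate measured over the last window (Hz)
#' @param theta_ema EMA coefficient in (0, 1]
#' @return the updated threshold
#' @export
update_theta <- function(theta, r_post_window, theta_ema) {
  stopifnot(theta_ema > 0, theta_ema <= 1)
  (1 - theta_ema) * theta + theta_ema * r_post_window
}

make_bcm_state <- function(pre, post, d) {
  idx <- make_syn_index(pre, post, d)
  c(idx, list(syn_pre_idx = match(pre, idx$upre),
              r_pre = numeric(length(idx$upre)),
              r_post = numeric(length(idx$upost)),
              theta = rep(NA_real_, length(idx$upost))))
}

# one batched BCM pass over window [t0, t1); pre_q holds bitmap-collapsed
# pre spikes, post_n exact post spike counts per unique post neuron
bcm_pass <- function(params, pst, w, t0, t1, pre_q, post_n) {
  span_s <- (t1 - t0) / 1000
  pre_cnt <- tabulate(match(pre_q$id[pre_q$id %in% pst$upre], pst$upre),
                      length(pst$upre))
  inst_pre <- pre_cnt / span_s
  inst_post <- post_n / span_s
  lp <- params$rate_lp
  pst$r_pre <- (1 - lp) * pst$r_pre + lp * inst_pre
  pst$r_post <- (1 - lp) * pst$r_post + lp * inst_post
  if (anyNA(pst$theta)) {  # first window: configured prior or measured rate
    init <- if (is.finite(params$theta0 %||% NA)) params$theta0
            else pst$r_post[is.na(pst$theta)]
    pst$theta[is.na(pst$theta)] <- init
  }
  dw <- bcm_dw(pst$r_pre[pst$syn_pre_idx], pst$r_post[pst$post_idx],
               pst$theta[pst$post_idx], w, params, span_s)
  pst$theta <- update_theta(pst$theta, inst_post, params$theta_ema)
  list(w = pmin(pmax(w + dw, params$w_min), params$w_max), pst = pst)
}
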