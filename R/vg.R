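# Voltage-gated bistable STDP.  Weight jumps are triggered at presynaptic
# spike arrival times (spike + delay): potentiation by `a` when the
# postsynaptic membrane was above theta_v at the arrival millisecond and
# the calcium trace lies in the potentiation eligibility interval;
# depression by `b` when the membrane was at or below theta_v and calcium
# lies in the depression interval.  Outside these events the weight drifts
# toward one of the two stable states w_min / w_max, with the branch chosen
# by comparing the window-start weight against theta_w (up at rate alpha
# above it, down at rate beta at or below it).  The membrane gate uses a
# 1 ms bitmap of V(t) > theta_v recorded by the neural loop, with V taken
# at the start of each millisecond (the value the arriving spike "sees").

make_vg_state <- function(pre, post, d) {
  idx <- make_syn_index(pre, post, d)
  c(idx, list(Cc = numeric(length(idx$upost)),
              pend_syn = integer(0), pend_a = numeric(0)))
}

# calcium value per (arrival, post) pair: exact decay of the carried trace
# plus contributions of this window's post spikes (bin centres, with
# multiplicities) that are at or before each arrival
vg_calcium_at <- function(pst, params, t0, da, dpost_idx, post_qc) {
  cc <- pst$Cc[dpost_idx] * exp(-(da - t0) / params$tau_c)
  for (q in sort(unique(post_qc$time))) {
    at_q <- post_qc$time == q
    cnt <- numeric(length(pst$upost))
    cnt[post_qc$idx[at_q]] <- post_qc$count[at_q]
    m <- da >= q
    cc[m] <- cc[m] + params$j_c * cnt[dpost_idx[m]] * exp(-(da[m] - q) /
                                                            params$tau_c)
  }
  cc
}

# one batched voltage-gated pass over window [t0, t1); vmat is the logical
# V > theta_v bitmap, rows = ms t0..t1-1, columns = unique post neurons
vg_pass <- function(params, pst, w, t0, t1, pre_q, post_qc, vmat) {
  if (is.null(vmat))
    stop("voltage-gated rule needs a membrane bitmap: configuration error")
  arr <- expand_arrivals(pst, pre_q)
  syn <- c(pst$pend_syn, arr$syn)
  a <- c(pst$pend_a, arr$a)
  due <- a < t1
  dsyn <- syn[due]; da <- a[due]
  dw <- numeric(pst$S)
  if (length(dsyn)) {
    dpost <- pst$post_idx[dsyn]
    row <- floor(da) - t0 + 1
    vbit <- vmat[cbind(row, dpost)]
    cc <- vg_calcium_at(pst, params, t0, da, dpost, post_qc)
    pot <- vbit & cc >= params$theta_h_down & cc < params$theta_h_up
    dep <- !vbit & cc >= params$theta_l_down & cc < params$theta_l_up
    dw <- group_sum(params$a * pot - params$b * dep, dsyn, pst$S)
  }
  drift <- ifelse(w > params$theta_w, params$alpha, -params$beta) * (t1 - t0)
  pst$Cc <- pst$Cc * exp(-(t1 - t0) / params$tau_c) +
    params$j_c * group_sum(post_qc$count * exp((post_qc$time - t1) /
                                                 params$tau_c),
                           post_qc$idx, length(pst$upost))
  pst$pend_syn <- syn[!due]
  pst$pend_a <- a[!due]
  list(w = pmin(pmax(w + dw + drift, params$w_min), params$w_max),
       pst = pst)
}

#' Apply one voltage-gated STDP pass to a single synaptic row
#'
#' Reference entry point mirroring [stdp_update_row()] for the voltage-
#' gated rule: presynaptic spikes are read from the row's window bitmap at
#' bin centres and shifted by each entry's delay; the per-millisecond
#' membrane bitmap and the postsynaptic spike times of the same phase
#' provide the gates.  Calcium state and deferred arrivals carry over via
#' `state`.
#'
#' @param row a [synaptic_row()]
#' @param pre_window a completed [spike_window()] of the presynaptic neuron
#' @param voltage_bits named list (by postsynaptic index) of logical
#'   vectors, one element per millisecond of the window, TRUE where
#'   V > theta_v
#' @param post_spikes named list (by postsynaptic index) of raw
#'   postsynaptic spike times within the window
#' @param params a [vg_params()] object
#' @param state carry-over state from the previous pass, or `NULL`
#' @return `list(row = <updated row>, state = <carry-over state>)`
#' @export
vg_update_row <- function(row, pre_window, voltage_bits, post_spikes,
                          params, state = NULL) {
  if (is.null(state)) state <- make_vg_state(rep(row$pre_id,
                                                 length(row$post)),
                                             row$post, row$d)
  t0 <- pre_window$phase_start
  t1 <- t0 + pre_window$window_ms
  pre_t <- t0 + (which(pre_window$bits) - 1) * pre_window$bin_ms +
    pre_window$bin_ms / 2
  pre_q <- list(id = rep(row$pre_id, length(pre_t)), time = pre_t)
  qid <- integer(0); qt <- numeric(0); qc <- integer(0)
  for (nm in names(post_spikes)) {
    tt <- post_spikes[[nm]]
    if (!length(tt)) next
    bin <- floor((tt - t0) / pre_window$bin_ms)
    cnt <- table(bin)
    qid <- c(qid, rep(match(as.integer(nm), state$upost), length(cnt)))
    qt <- c(qt, t0 + as.integer(names(cnt)) * pre_window$bin_ms +
              pre_window$bin_ms / 2)
    qc <- c(qc, as.integer(cnt))
  }
  vmat <- matrix(FALSE, t1 - t0, length(state$upost))
  for (nm in names(voltage_bits))
    vmat[, match(as.integer(nm), state$upost)] <- voltage_bits[[nm]]
  res <- vg_pass(params, state, row$w, t0, t1, pre_q,
                 list(idx = qid, time = qt, count = qc), vmat)
  row$w <- res$w
  list(row = row, state = res$pst)
}
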