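# Trace-based STDP operating on completed spike windows.
#
# Pairing is all-to-all: the total update equals the sum of F(dt) over all
# (pre, post) spike pairs, with dt = (t_pre + d) - t_post, i.e. presynaptic
# times are shifted by the synaptic delay before comparison (the delay is
# reintroduced at the postsynaptic end, so ignoring it would mis-time every
# pair).  Instead of enumerating pairs, each synapse carries an exponential
# trace of its *arrival* times (pre spikes + delay) and each postsynaptic
# neuron carries a trace of its spikes:
#   - at every post spike the weight grows by a_plus times the arrival
#     trace (pairs with dt < 0),
#   - at every arrival the weight shrinks by a_minus times the post trace
#     (pairs with dt >= 0; a coincident pair counts as depression, F(0) =
#     -a_minus).
# Traces are advanced exactly, carry over across windows, and arrivals that
# fall beyond the current window (large delays) are deferred to the pass
# that owns them, so the batched result matches the explicit all-pairs sum
# to floating-point accuracy for arbitrary delays.

#' The STDP pair kernel F(dt)
#'
#' @param delta_t time difference `t_pre - t_post` (ms), after delay shift
#' @param params an [stdp_params()] object
#' @return the weight change contributed by one spike pair: positive
#'   (potentiation) for `delta_t < 0`, negative (depression) for
#'   `delta_t >= 0`
#' @examples
#' p <- stdp_params(a_plus = 1, a_minus = 1)
#' stdp_F(-p$tau_plus, p)  # exp(-1)
#' stdp_F(0, p)            # -a_minus
#' @export
stdp_F <- function(delta_t, params) {
  ifelse(delta_t < 0,
         params$a_plus * exp(delta_t / params$tau_plus),
         -params$a_minus * exp(-delta_t / params$tau_minus))
}

# shared plastic-projection indexing: synapse arrays grouped by pre neuron
# for expanding pre-spike events into per-synapse arrival events
make_syn_index <- function(pre, post, d) {
  S <- length(pre)
  upre <- sort(unique(pre))
  upost <- sort(unique(post))
  o <- order(pre)
  fan <- tabulate(match(pre, upre), length(upre))
  list(S = S, upre = upre, upost = upost,
       post_idx = match(post, upost),
       syn_sorted = o, row_start = c(0L, cumsum(fan))[seq_along(upre)] + 1L,
       fan = fan, d = d,
       syn_by_post = split(seq_len(S), match(post, upost)))
}

make_stdp_state <- function(pre, post, d) {
  idx <- make_syn_index(pre, post, d)
  c(idx, list(X = numeric(idx$S), Y = numeric(length(idx$upost)),
              pend_syn = integer(0), pend_a = numeric(0)))
}

# expand quantized pre-spike events (global id, bin-centre time) into
# per-synapse arrival events (synapse index, time + delay)
expand_arrivals <- function(pst, pre_q) {
  keep <- pre_q$id %in% pst$upre
  if (!any(keep)) return(list(syn = integer(0), a = numeric(0)))
  id <- match(pre_q$id[keep], pst$upre)
  tt <- pre_q$time[keep]
  cnt <- pst$fan[id]
  syn <- pst$syn_sorted[sequence(cnt, from = pst$row_start[id])]
  list(syn = syn, a = rep(tt, cnt) + pst$d[syn])
}

group_sum <- function(values, group, n) {
  out <- numeric(n)
  if (length(values)) {
    rs <- rowsum(values, group)
    out[as.integer(rownames(rs))] <- rs[, 1]
  }
  out
}

# one batched STDP pass over window [t0, t1)
stdp_pass <- function(params, pst, w, t0, t1, pre_q, post_q) {
  arr <- expand_arrivals(pst, pre_q)
  syn <- c(pst$pend_syn, arr$syn)
  a <- c(pst$pend_a, arr$a)
  due <- a < t1
  dsyn <- syn[due]; da <- a[due]
  tp <- params$tau_plus; tm <- params$tau_minus
  dw <- numeric(pst$S)

  keep <- post_q$id %in% pst$upost
  pid <- match(post_q$id[keep], pst$upost)
  ptime <- post_q$time[keep]
  ptimes <- sort(unique(ptime))

  # potentiation: at each post-spike time, read the arrival trace
  for (p in ptimes) {
    posts <- pid[ptime == p]
    sel <- unlist(pst$syn_by_post[as.character(posts)], use.names = FALSE)
    if (!length(sel)) next
    contrib <- group_sum(exp((da[da < p] - p) / tp), dsyn[da < p], pst$S)
    val <- pst$X * exp(-(p - t0) / tp) + contrib
    dw[sel] <- dw[sel] + params$a_plus * val[sel]
  }

  # depression: at each due arrival, read the postsynaptic trace
  if (length(dsyn)) {
    y <- pst$Y[pst$post_idx[dsyn]] * exp(-(da - t0) / tm)
    for (p in ptimes) {
      posts <- pid[ptime == p]
      flag <- logical(length(pst$upost)); flag[posts] <- TRUE
      m <- flag[pst$post_idx[dsyn]] & (da >= p)
      y[m] <- y[m] + exp(-(da[m] - p) / tm)
    }
    dw <- dw - params$a_minus * group_sum(y, dsyn, pst$S)
  }

  # advance traces to t1 and clip weights
  pst$X <- pst$X * exp(-(t1 - t0) / tp) +
    group_sum(exp((da - t1) / tp), dsyn, pst$S)
  pst$Y <- pst$Y * exp(-(t1 - t0) / tm) +
    group_sum(exp((ptime - t1) / tm), pid, length(pst$upost))
  pst$pend_syn <- syn[!due]
  pst$pend_a <- a[!due]
  list(w = pmin(pmax(w + dw, params$w_min), params$w_max), pst = pst)
}

#' Apply one batched STDP pass to a single synaptic row
#'
#' Reference entry point for updating the synapses of one presynaptic
#' neuron from a completed spike window: presynaptic spike times are read
#' from the row's window bitmap at bin centres, shifted by each entry's
#' delay, and combined with the postsynaptic windows under all-to-all
#' pairing.  Trace state (and arrivals deferred past the window end)
#' carries over between calls via `state`.
#'
#' @param row a [synaptic_row()]
#' @param pre_window a completed [spike_window()] for the presynaptic neuron
#' @param post_windows a named list (by postsynaptic index) of completed
#'   [spike_window()]s covering the same phase
#' @param params an [stdp_params()] object
#' @param state carry-over state from the previous pass, or `NULL` for the
#'   first window
#' @return `list(row = <updated row>, state = <carry-over state>)`
#' @export
stdp_update_row <- function(row, pre_window, post_windows, params,
                            state = NULL) {
  if (is.null(state)) state <- make_stdp_state(rep(row$pre_id,
                                                   length(row$post)),
                                               row$post, row$d)
  t0 <- pre_window$phase_start
  t1 <- t0 + pre_window$window_ms
  centres <- function(win) win$phase_start +
    (which(win$bits) - 1) * win$bin_ms + win$bin_ms / 2
  pre_t <- centres(pre_window)
  pre_q <- list(id = rep(row$pre_id, length(pre_t)), time = pre_t)
  post_id <- integer(0); post_t <- numeric(0)
  for (nm in names(post_windows)) {
    ct <- centres(post_windows[[nm]])
    post_id <- c(post_id, rep(as.integer(nm), length(ct)))
    post_t <- c(post_t, ct)
  }
  res <- stdp_pass(params, state, row$w, t0, t1, pre_q,
                   list(id = post_id, time = post_t))
  row$w <- res$w
  list(row = row, state = res$pst)
}
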