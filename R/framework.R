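# Batched plasticity scheduling.  The neural loop records spikes into the
# current window while the plasticity pass consumes the completed previous
# window; here the two are serialised: at each boundary the pass for the
# window that just closed runs before recording continues, which preserves
# the reader/writer contract (the pass sees exactly one completed window)
# without real concurrency.  Every pass walks all rows of the plastic
# projection, so one weight write-back per row is counted per pass,
# independent of activity -- the accounting that distinguishes the batched
# schedule from per-pre-spike (deferred event driven, DED) updating.

init_plastic_state <- function(proj) {
  switch(proj$rule$name,
    stdp_trace = make_stdp_state(proj$pre, proj$post, proj$d),
    bcm = make_bcm_state(proj$pre, proj$post, proj$d),
    vg_stdp = make_vg_state(proj$pre, proj$post, proj$d),
    stop("unknown rule name: ", proj$rule$name))
}

#' Create a write-back ledger for a plastic projection
#'
#' Tracks, per synaptic row (one row per presynaptic neuron), how many
#' times the row's weights are committed back to the weight store.  Both
#' accountings are kept: `batched` increments once per row per completed
#' plasticity pass; `ded` (deferred event driven) increments once per
#' presynaptic spike, the write-back cost a per-pre-spike update scheme
#' would pay.
#'
#' @param n_rows number of synaptic rows (presynaptic neurons)
#' @return a `writeback_ledger` object
#' @export
writeback_ledger <- function(n_rows) {
  structure(list(batched = numeric(n_rows), ded = numeric(n_rows),
                 n_rows = n_rows),
            class = "writeback_ledger")
}

#' Count per-row weight write-backs
#'
#' Either reads a [writeback_ledger()] filled during a run, or computes the
#' analytic count: in batched mode the number of plasticity windows
#' starting within `[0, duration)`; in per-pre-spike (`"ded"`) mode the
#' number of presynaptic spikes.
#'
#' @param ledger a [writeback_ledger()] from a run, or `NULL` to use the
#'   analytic form
#' @param mode `"batched"` or `"ded"`
#' @param duration simulated duration (ms); analytic form only
#' @param pre_spike_times presynaptic spike times (ms); analytic `"ded"`
#'   form only
#' @param window_ms plasticity window span (ms)
#' @return per-row counts (ledger form) or a single count (analytic form)
#' @examples
#' count_writebacks(mode = "batched", duration = 1000)            # 8
#' count_writebacks(mode = "ded",
#'                  pre_spike_times = seq(0, 999, length.out = 24),
#'                  duration = 1000)                              # 24
#' @export
count_writebacks <- function(ledger = NULL, mode = c("batched", "ded"),
                             duration = NULL, pre_spike_times = NULL,
                             window_ms = 128) {
  mode <- match.arg(mode)
  if (!is.null(ledger))
    return(if (mode == "batched") ledger$batched else ledger$ded)
  stopifnot(!is.null(duration), duration > 0)
  if (mode == "batched") ceiling(duration / window_ms)
  else sum(pre_spike_times < duration)
}

#' Run one batched plasticity pass over a plastic projection
#'
#' Applies the projection's rule to the completed window `[t0, t1)`: every
#' row is visited exactly once, weight changes are accumulated and clipped
#' to the rule's bounds, rule state (traces, calcium, rates, threshold,
#' deferred arrivals) is advanced, and one write-back per row is recorded
#' in the projection's ledger.  Rules with relaxation terms (BCM decay,
#' voltage-gated drift) change weights even when the window is empty, which
#' is why the pass always runs.
#'
#' @param proj a realised plastic projection from [network()], carrying
#'   `$w`, `$rule` and (after the first pass) `$pstate` and `$ledger`
#' @param window numeric `c(t0, t1)` of the completed window (ms)
#' @param pre_spikes `list(id =, time =)` of raw presynaptic spikes
#'   (global ids) within the window
#' @param post_spikes `list(id =, time =)` of raw postsynaptic spikes
#'   within the window
#' @param v_before optional numeric matrix of membrane potentials (rows =
#'   ms of the window, columns = the projection's postsynaptic neurons in
#'   increasing global id order); required by the voltage-gated rule
#' @param bin_ms spike-history bitmap resolution (ms)
#' @return the updated projection
#' @export
run_plasticity_pass <- function(proj, window, pre_spikes, post_spikes,
                                v_before = NULL, bin_ms = 2) {
  stopifnot(isTRUE(proj$plastic))
  t0 <- window[1]; t1 <- window[2]
  if (is.null(proj$pstate)) proj$pstate <- init_plastic_state(proj)
  if (is.null(proj$ledger)) proj$ledger <- writeback_ledger(proj$n_pre)
  pst <- proj$pstate
  prm <- proj$rule$params

  pre_q <- quantize_spikes(pre_spikes$time, pre_spikes$id, t0, bin_ms)
  res <- switch(proj$rule$name,
    stdp_trace = {
      post_q <- quantize_spikes(post_spikes$time, post_spikes$id, t0,
                                bin_ms)
      stdp_pass(prm, pst, proj$w, t0, t1, pre_q, post_q)
    },
    bcm = {
      post_n <- tabulate(match(post_spikes$id[post_spikes$id %in%
                                                pst$upost], pst$upost),
                         length(pst$upost))
      bcm_pass(prm, pst, proj$w, t0, t1, pre_q, post_n)
    },
    vg_stdp = {
      keep <- post_spikes$id %in% pst$upost
      bin <- floor((post_spikes$time[keep] - t0) / bin_ms)
      pidx <- match(post_spikes$id[keep], pst$upost)
      key <- paste(pidx, bin)
      first <- !duplicated(key)
      post_qc <- list(idx = pidx[first],
                      time = t0 + bin[first] * bin_ms + bin_ms / 2,
                      count = as.integer(table(key)[key[first]]))
      vmat <- if (is.null(v_before)) NULL else v_before > prm$theta_v
      vg_pass(prm, pst, proj$w, t0, t1, pre_q, post_qc, vmat)
    },
    stop("unknown rule name: ", proj$rule$name))

  proj$w <- res$w
  proj$pstate <- res$pst
  proj$ledger$batched <- proj$ledger$batched + 1
  if (length(pre_spikes$id))  # DED accounting: one write-back per pre spike
    proj$ledger$ded <- proj$ledger$ded +
      tabulate(pre_spikes$id - (proj$src_offset %||% 0L), proj$n_pre)
  proj
}
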