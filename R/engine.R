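# Simulation driver.  The compiled kernel advances the network one
# plasticity window at a time (1 ms steps inside); at every window boundary
# the batched plasticity passes run on the spikes of the window that just
# closed, weights are written back, and the next window starts with the
# updated weights.  All randomness (stimuli) is drawn up front from named
# sub-streams of the run seed, so identical (network, duration, seed)
# produce bit-identical recordings.

gen_population_stimulus <- function(pop, offset, duration, seed) {
  st <- pop$stimulus
  acc_t <- list(); acc_i <- list()
  add <- function(tt, id) {
    tt <- tt[tt >= 0 & tt < duration]
    k <- length(acc_t) + 1L
    acc_t[[k]] <<- tt; acc_i[[k]] <<- rep(id, length(tt))
  }
  with_seed(seed, switch(st$type,
    poisson = {
      p <- min(st$rate / 1000, 1)
      t_on <- max(0, st$start %||% 0)
      t_off <- min(duration, st$stop %||% duration)
      if (t_off > t_on)
        for (j in seq_len(pop$n)) add(bernoulli_slots(p, t_on, t_off), j)
    },
    schedule = {
      for (j in seq_len(pop$n)) add(st$times[[j]], j)
    },
    rate_schedule = {
      for (s in seq_along(st$onsets)) {
        t_on <- st$onsets[s]
        t_off <- min(duration, t_on + st$duration)
        if (t_off <= t_on) next
        for (j in seq_len(pop$n)) {
          p <- min(st$rates[s, j] / 1000, 1)
          if (p > 0) add(bernoulli_slots(p, t_on, t_off), j)
        }
      }
    },
    stop("unknown stimulus type: ", st$type)))
  times <- unlist(acc_t) %||% numeric(0)
  ids <- unlist(acc_i) %||% integer(0)
  list(time = times, id = ids + offset)
}

#' Simulate a network
#'
#' Runs the discrete-time (1 ms) simulation for `duration_ms` milliseconds.
#' Within every step the order of events is fixed: scheduled stimulus
#' spikes are emitted and delivered, ring-buffer slots for the current
#' millisecond are consumed, and LIF neurons are updated (so a spike
#' arriving at t can influence the spike emitted at t).  At each plasticity
#' window boundary (every `window_ms`, plus a final partial window at the
#' end of the run) the batched passes of all plastic projections run on the
#' completed window and one write-back per row is recorded.
#'
#' @param net a [network()] object
#' @param duration_ms simulated duration (ms)
#' @param seed integer master seed for the stimulus sub-streams
#' @param record_v global neuron ids whose membrane potential is recorded
#'   every millisecond (empty for none)
#' @param snapshots `"none"`, `"boundaries"` (weights of every plastic
#'   projection at every window boundary) or `"final"`
#' @return a `recording_set` with elements `spikes`
#'   (`data.frame(time_ms, neuron_id)`), `v` (matrix, one column per
#'   recorded neuron), `snapshots`, `weights` (final weights per
#'   projection), `ledgers` (per plastic projection), `projections` (the
#'   final projection objects) and run metadata
#' @export
run_network <- function(net, duration_ms, seed = 1,
                        record_v = integer(0),
                        snapshots = c("boundaries", "none", "final")) {
  snapshots <- match.arg(snapshots)
  duration_ms <- as.integer(duration_ms)
  N <- net$n_neurons
  pops <- net$populations
  pnames <- vapply(pops, `[[`, "", "name")

  # flat per-neuron parameter vectors
  is_lif <- logical(N)
  v_rest <- v_reset <- v_thresh <- em <- es <- c_syn <- c_off <- numeric(N)
  t_refrac <- integer(N)
  v0 <- numeric(N)
  for (p in pops) {
    idx <- net$offsets[[p$name]] + seq_len(p$n)
    if (p$model == "lif") {
      is_lif[idx] <- TRUE
      pr <- lif_propagators(p$params)
      v_rest[idx] <- p$params$v_rest; v_reset[idx] <- p$params$v_reset
      v_thresh[idx] <- p$params$v_thresh
      em[idx] <- pr$em; es[idx] <- pr$es
      c_syn[idx] <- pr$c_syn; c_off[idx] <- pr$c_off
      t_refrac[idx] <- p$params$t_refrac
      # start at the steady state (bias current included)
      v0[idx] <- p$params$v_rest + p$params$r_m * p$params$i_offset
    }
  }

  projs <- net$projections
  max_d <- max(c(1L, unlist(lapply(projs, `[[`, "d"))))
  buf_len <- max_d + 2L

  # per-projection CSR over presynaptic global id (0-based for C++)
  csr <- lapply(projs, function(pr) {
    o <- order(pr$pre)
    list(ord = o,
         row_ptr = c(0L, cumsum(tabulate(pr$pre, N))),
         post = as.integer(pr$post[o] - 1L),
         d = as.integer(pr$d[o]),
         lane = if (pr$receptor == "exc") 0L else 1L)
  })

  # stimuli, drawn up front and split into windows
  stim_t <- numeric(0); stim_id <- integer(0)
  for (p in pops) {
    if (p$model != "source") next
    sp <- gen_population_stimulus(p, net$offsets[[p$name]], duration_ms,
                                  sub_seed(seed, paste0("stim:", p$name)))
    stim_t <- c(stim_t, sp$time); stim_id <- c(stim_id, sp$id)
  }
  o <- order(stim_t, stim_id)
  stim_t <- as.integer(stim_t[o]); stim_id <- stim_id[o]

  # plastic projections: state, ledgers, voltage gating set
  plastic <- which(vapply(projs, function(p) isTRUE(p$plastic), TRUE))
  for (k in plastic) {
    projs[[k]]$pstate <- init_plastic_state(projs[[k]])
    projs[[k]]$ledger <- writeback_ledger(projs[[k]]$n_pre)
  }
  vg_projs <- plastic[vapply(projs[plastic],
                             function(p) p$rule$name == "vg_stdp", TRUE)]
  vgate <- sort(unique(unlist(lapply(projs[vg_projs],
                                     function(p) p$pstate$upost))))

  state <- list(v = v0, ise = numeric(N), isi = numeric(N),
                refrac = integer(N),
                buf_e = matrix(0, buf_len, N),
                buf_i = matrix(0, buf_len, N))

  spikes_t <- list(); spikes_id <- list(); seg <- 0L
  v_chunks <- list()
  snaps <- list()
  record_v <- as.integer(record_v)

  # window segmentation of the stimulus stream
  n_win <- if (duration_ms > 0) ceiling(duration_ms / net$window_ms) else 0L
  if (length(stim_t)) {
    w_of <- stim_t %/% net$window_ms + 1L
    cnt <- tabulate(w_of, n_win)
    w_ptr <- c(0L, cumsum(cnt))
  } else w_ptr <- integer(n_win + 1L)

  take_snapshot <- function(t) {
    if (snapshots == "none" || !length(plastic)) return()
    snaps[[length(snaps) + 1L]] <<- list(
      t = t,
      w = stats::setNames(lapply(projs[plastic], `[[`, "w"),
                          vapply(projs[plastic], `[[`, "", "name")))
  }
  t0 <- 0L
  while (t0 < duration_ms) {
    seg <- seg + 1L
    t1 <- min(t0 + net$window_ms, duration_ms)
    idx <- if (length(stim_t)) seq_len(w_ptr[seg + 1L] - w_ptr[seg]) +
      w_ptr[seg] else integer(0)
    eng_projs <- lapply(seq_along(projs), function(k)
      c(csr[[k]], list(w = projs[[k]]$w[csr[[k]]$ord])))
    out <- cpp_run_segment(t0, t1, is_lif, v_rest, v_reset, v_thresh,
                           em, es, c_syn, c_off, t_refrac,
                           state$v, state$ise, state$isi, state$refrac,
                           state$buf_e, state$buf_i, eng_projs,
                           stim_t[idx], as.integer(stim_id[idx] - 1L),
                           record_v - 1L, as.integer(vgate - 1L))
    state <- list(v = out$v, ise = out$ise, isi = out$isi,
                  refrac = out$refrac, buf_e = out$buf_e,
                  buf_i = out$buf_i)
    st <- out$spike_t; sid <- out$spike_id + 1L
    spikes_t[[seg]] <- st; spikes_id[[seg]] <- sid
    if (length(record_v)) v_chunks[[seg]] <- out$v_trace

    for (k in plastic) {
      pr <- projs[[k]]
      src <- neuron_ids(net, pr$source)
      tgt <- neuron_ids(net, pr$target)
      pre_m <- sid >= src[1] & sid <= src[length(src)]
      post_m <- sid >= tgt[1] & sid <= tgt[length(tgt)]
      vb <- NULL
      if (pr$rule$name == "vg_stdp")
        vb <- out$v_before[, match(pr$pstate$upost, vgate), drop = FALSE]
      projs[[k]] <- run_plasticity_pass(
        pr, c(t0, t1),
        list(id = sid[pre_m], time = st[pre_m]),
        list(id = sid[post_m], time = st[post_m]),
        v_before = vb, bin_ms = net$bin_ms)
    }
    if (snapshots == "boundaries") take_snapshot(t1)
    t0 <- t1
  }
  if (snapshots == "final" && duration_ms > 0) take_snapshot(duration_ms)

  spikes <- data.frame(time_ms = unlist(spikes_t) %||% integer(0),
                       neuron_id = unlist(spikes_id) %||% integer(0))
  if (nrow(spikes) == 0)
    spikes <- data.frame(time_ms = integer(0), neuron_id = integer(0))
  v <- if (length(record_v) && length(v_chunks))
    do.call(rbind, v_chunks) else NULL
  if (!is.null(v)) colnames(v) <- as.character(record_v)

  structure(list(
    spikes = spikes, v = v, v_ids = record_v, snapshots = snaps,
    weights = stats::setNames(lapply(projs, `[[`, "w"),
                              vapply(projs, `[[`, "", "name")),
    ledgers = stats::setNames(lapply(projs[plastic], `[[`, "ledger"),
                              vapply(projs[plastic], `[[`, "", "name")),
    projections = projs,
    duration_ms = duration_ms, seed = seed,
    window_ms = net$window_ms, bin_ms = net$bin_ms,
    sizes = net$sizes, offsets = net$offsets),
    class = "recording_set")
}

#' Spike times of one neuron or population
#'
#' @param rec a `recording_set` from [run_network()]
#' @param ids global neuron ids
#' @return numeric vector of spike times (ms)
#' @export
spike_times <- function(rec, ids) {
  rec$spikes$time_ms[rec$spikes$neuron_id %in% ids]
}
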