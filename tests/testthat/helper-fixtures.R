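# Small builders shared across the test files.  Everything is generated in
# code; no fixture files.

# one scheduled source feeding one LIF neuron through a single synapse
single_synapse_net <- function(spike_times, w, d = 1, lif = lif_params(),
                               plastic = FALSE, rule = NULL) {
  pops <- list(
    population("in", 1, "source",
               stimulus = list(type = "schedule",
                               times = list(spike_times))),
    population("out", 1, "lif", params = lif))
  prj <- list(projection("in", "out", list(type = "one_to_one"),
                         weight = w, delay = d, plastic = plastic,
                         rule = rule))
  network(pops, prj, seed = 1)
}

# brute-force all-pairs STDP oracle on 2 ms bin-centre quantized spikes;
# delta_t = (pre + d) - post over every pair
stdp_allpairs_oracle <- function(pre, post, d, prm, bin_ms = 2) {
  q <- function(t) unique(bin_ms * floor(t / bin_ms) + bin_ms / 2)
  a <- q(pre) + d
  p <- q(post)
  if (!length(a) || !length(p)) return(0)
  sum(outer(a, p, function(x, y) stdp_F(x - y, prm)))
}

# drive stdp_update_row over consecutive windows covering [0, n_win*128)
run_stdp_windows <- function(pre, post, d, prm, n_win, w0 = 0) {
  row <- synaptic_row(1, post = 2, w = w0, d = d)
  st <- NULL
  for (k in seq_len(n_win) - 1) {
    t0 <- k * 128
    pw <- spike_window(t0)
    for (t in pre[pre >= t0 & pre < t0 + 128])
      pw <- record_pre_spike(pw, t)
    ow <- spike_window(t0)
    for (t in post[post >= t0 & post < t0 + 128])
      ow <- record_pre_spike(ow, t)
    res <- stdp_update_row(row, pw, list(`2` = ow), prm, st)
    row <- res$row
    st <- res$state
  }
  row$w
}
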