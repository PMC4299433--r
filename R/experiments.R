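# Scripted reproductions of classical plasticity experiments, desk scale.
# Every experiment is a pure function of its parameters and a seed; the
# quantitative analysis metrics are computed only from the returned
# recordings and weight snapshots.  Neuron and rule constants that the
# classical protocols leave open are fixture defaults here, with initial
# weights constructed from the closed-form LIF calibration ("n spikes just
# reach threshold") rather than tuned by hand.

#' Count input spikes preceding the first postsynaptic spike
#'
#' For each presentation (delimited by consecutive onsets), counts the
#' input spikes whose *arrival* (emission time plus the projection delay)
#' is no later than the first postsynaptic spike of the presentation --
#' the spikes that could causally contribute to that firing.  If the
#' postsynaptic neuron never fires during a presentation the count is `NA`
#' (the "no-spike" sentinel); if it fires before any input has arrived the
#' count is 0.
#'
#' @param rec a `recording_set` from [run_network()]
#' @param pattern_onsets presentation onset times (ms)
#' @param input_ids global ids of the input neurons
#' @param post_ids global ids of the postsynaptic neuron(s)
#' @param delay projection delay added to input spike times (ms)
#' @return integer vector, one count per presentation (`NA` = no spike)
#' @export
spikes_to_fire <- function(rec, pattern_onsets, input_ids, post_ids,
                           delay = 0) {
  ends <- c(pattern_onsets[-1], Inf)
  in_t <- spike_times(rec, input_ids)
  po_t <- spike_times(rec, post_ids)
  vapply(seq_along(pattern_onsets), function(i) {
    o <- pattern_onsets[i]; e <- ends[i]
    first <- suppressWarnings(min(po_t[po_t >= o & po_t < e]))
    if (!is.finite(first)) return(NA_integer_)
    sum(in_t >= o & in_t < e & (in_t + delay) <= first)
  }, integer(1))
}

experiment_result <- function(name, recordings, metrics, config,
                              snapshots = NULL) {
  structure(list(name = name, recordings = recordings,
                 weight_snapshots = snapshots %||% recordings$snapshots,
                 metrics = metrics, config = config),
            class = "experiment_result")
}

#' Single-synapse burst potentiation experiment
#'
#' A single input neuron fires a short burst (`n_spikes` spikes,
#' `isi_ms` apart) every `period_ms` through one plastic synapse onto a
#' LIF neuron.  The initial weight is calibrated from the closed-form LIF
#' response so that exactly `n_spikes` spikes first cross threshold; the
#' weight bound is `w_max_factor` times that.  Under potentiation-dominant
#' STDP (`a_minus = 0`) the synapse saturates at the bound and the neuron
#' fires after only two input spikes.
#'
#' @param n_spikes spikes per burst (default 3)
#' @param isi_ms intra-burst inter-spike interval (ms)
#' @param period_ms burst period (ms)
#' @param duration_ms simulated time (ms)
#' @param w_max_factor weight bound as a multiple of the calibrated weight
#' @param a_plus_frac potentiation amplitude as a fraction of the
#'   calibrated weight
#' @param a_minus depression amplitude (0 = potentiation-dominant)
#' @param lif LIF parameters; the default uses fast time constants so the
#'   two-spike response crosses threshold before the third spike arrives
#' @param seed master seed
#' @return an `experiment_result`; metrics: `spikes_to_fire` per
#'   presentation, `initial`, `final`, `w_final`
#' @export
run_burst_experiment <- function(n_spikes = 3, isi_ms = 2, period_ms = 50,
                                 duration_ms = 640, w_max_factor = 1.6,
                                 a_plus_frac = 0.25, a_minus = 0,
                                 lif = lif_params(tau_m = 10, tau_syn = 1,
                                                  t_refrac = 2),
                                 seed = 1) {
  onsets <- seq(0, duration_ms - period_ms, by = period_ms)
  burst <- (seq_len(n_spikes) - 1) * isi_ms
  w0 <- calibrate_weight(lif, burst)
  prm <- stdp_params(a_plus = a_plus_frac * w0, a_minus = a_minus,
                     w_min = 0, w_max = w_max_factor * w0)
  pops <- list(
    population("in", 1, "source",
               stimulus = list(type = "schedule",
                               times = list(as.vector(outer(burst,
                                                            onsets, "+"))))),
    population("out", 1, "lif", params = lif))
  prj <- list(projection("in", "out", list(type = "one_to_one"),
                         weight = w0, delay = 1, plastic = TRUE,
                         rule = list(name = "stdp_trace", params = prm)))
  net <- network(pops, prj, seed = seed)
  rec <- run_network(net, duration_ms, seed = seed, snapshots = "boundaries")
  stf <- spikes_to_fire(rec, onsets, neuron_ids(net, "in"),
                        neuron_ids(net, "out"), delay = 1)
  experiment_result("burst_stdp", rec,
                    metrics = list(spikes_to_fire = stf, initial = stf[1],
                                   final = stf[length(stf)],
                                   w0 = w0,
                                   w_final = rec$weights[["in->out"]]),
                    config = list(n_spikes = n_spikes, isi_ms = isi_ms,
                                  period_ms = period_ms,
                                  duration_ms = duration_ms,
                                  w_max_factor = w_max_factor, seed = seed))
}

#' Latency-reduction experiment (sequential input pattern)
#'
#' `n_inputs` input neurons fire once each, `isi_ms` apart, and the
#' pattern repeats every `period_ms`.  The initial weight is calibrated so
#' that at the first presentation all inputs are needed to reach
#' threshold; with bound `w_max_factor` times that and
#' potentiation-dominant STDP, the postsynaptic neuron ends up firing
#' after only two input spikes, i.e. with a much shorter latency from
#' pattern onset.
#'
#' @param n_inputs number of input neurons (default 10)
#' @inheritParams run_burst_experiment
#' @return an `experiment_result`; metrics: `spikes_to_fire` and
#'   `latency_ms` per presentation, `initial`, `final`
#' @export
run_latency_experiment <- function(n_inputs = 10, isi_ms = 2,
                                   period_ms = 50, duration_ms = 3000,
                                   w_max_factor = 5.5, a_plus_frac = 0.25,
                                   a_minus = 0,
                                   lif = lif_params(tau_m = 10, tau_syn = 2,
                                                    t_refrac = 2),
                                   seed = 1) {
  onsets <- seq(0, duration_ms - period_ms, by = period_ms)
  pattern <- (seq_len(n_inputs) - 1) * isi_ms
  w0 <- calibrate_weight(lif, pattern)
  prm <- stdp_params(a_plus = a_plus_frac * w0, a_minus = a_minus,
                     w_min = 0, w_max = w_max_factor * w0)
  times <- lapply(seq_len(n_inputs), function(k) onsets + pattern[k])
  pops <- list(
    population("in", n_inputs, "source",
               stimulus = list(type = "schedule", times = times)),
    population("out", 1, "lif", params = lif))
  prj <- list(projection("in", "out", list(type = "all_to_all"),
                         weight = w0, delay = 1, plastic = TRUE,
                         rule = list(name = "stdp_trace", params = prm)))
  net <- network(pops, prj, seed = seed)
  rec <- run_network(net, duration_ms, seed = seed, snapshots = "final")
  out <- neuron_ids(net, "out")
  stf <- spikes_to_fire(rec, onsets, neuron_ids(net, "in"), out, delay = 1)
  po <- spike_times(rec, out)
  lat <- vapply(seq_along(onsets), function(i) {
    e <- c(onsets[-1], Inf)[i]
    first <- suppressWarnings(min(po[po >= onsets[i] & po < e]))
    if (is.finite(first)) first - onsets[i] else NA_real_
  }, numeric(1))
  experiment_result("latency", rec,
                    metrics = list(spikes_to_fire = stf, latency_ms = lat,
                                   initial = stf[1],
                                   final = stf[length(stf)], w0 = w0,
                                   w_final = rec$weights[["in->out"]]),
                    config = list(n_inputs = n_inputs, isi_ms = isi_ms,
                                  period_ms = period_ms,
                                  duration_ms = duration_ms,
                                  w_max_factor = w_max_factor, seed = seed))
}

#' Synaptic competition experiment (weight bimodality)
#'
#' A large group of uncorrelated Poisson inputs projects onto a single
#' LIF neuron through plastic synapses with uniformly distributed initial
#' weights.  Under additive, slightly depression-biased STDP
#' (`a_minus tau_minus > a_plus tau_plus`) the synapses compete and the
#' weight distribution splits into a strong and a weak group piled at the
#' bounds, regulating the output rate.
#'
#' @param n_inputs number of Poisson inputs (default 1000)
#' @param rate_hz input rate (Hz, default 20)
#' @param duration_ms simulated time (ms, default 300000 = 300 s)
#' @param w_max weight bound (nA)
#' @param init_frac range of initial weights as fractions of `w_max`
#' @param a_plus_frac potentiation amplitude as a fraction of `w_max`
#' @param depression_bias `a_minus / a_plus` ratio (> 1)
#' @param lif LIF parameters of the output neuron
#' @param plastic set `FALSE` to freeze weights (control)
#' @param seed master seed
#' @return an `experiment_result`; metrics: initial/final weight
#'   histograms, `bimodality_initial`, `bimodality_final` (fraction of
#'   weights within 10% of either bound), `post_rate_hz`
#' @export
run_song_experiment <- function(n_inputs = 1000, rate_hz = 20,
                                duration_ms = 300000, w_max = 4,
                                init_frac = c(0.4, 0.9),
                                a_plus_frac = 0.005,
                                depression_bias = 1.05,
                                lif = lif_params(t_refrac = 1),
                                plastic = TRUE, seed = 1) {
  prm <- stdp_params(a_plus = a_plus_frac * w_max,
                     a_minus = depression_bias * a_plus_frac * w_max,
                     w_min = 0, w_max = w_max)
  pops <- list(
    population("in", n_inputs, "source",
               stimulus = list(type = "poisson", rate = rate_hz,
                               start = 0, stop = duration_ms)),
    population("out", 1, "lif", params = lif))
  prj <- list(projection(
    "in", "out", list(type = "all_to_all"),
    weight = list(type = "uniform", min = init_frac[1] * w_max,
                  max = init_frac[2] * w_max),
    delay = 1, plastic = plastic,
    rule = if (plastic) list(name = "stdp_trace", params = prm) else NULL))
  net <- network(pops, prj, seed = seed)
  w_init <- net$projections[[1]]$w
  rec <- run_network(net, duration_ms, seed = seed, snapshots = "final")
  w_fin <- rec$weights[["in->out"]]
  bim <- function(w) mean(w <= 0.1 * w_max | w >= 0.9 * w_max)
  brk <- seq(0, w_max, length.out = 51)
  experiment_result("song", rec,
    metrics = list(
      hist_initial = hist(w_init, breaks = brk, plot = FALSE)$counts,
      hist_final = hist(w_fin, breaks = brk, plot = FALSE)$counts,
      hist_breaks = brk,
      bimodality_initial = bim(w_init), bimodality_final = bim(w_fin),
      w_initial = w_init, w_final = w_fin,
      post_rate_hz = 1000 * length(spike_times(rec,
        neuron_ids(net, "out"))) / duration_ms),
    config = list(n_inputs = n_inputs, rate_hz = rate_hz,
                  duration_ms = duration_ms, w_max = w_max, seed = seed,
                  plastic = plastic))
}

# spike counts per (segment, unit) with proper accumulation
count_by_segment <- function(times, units, seg_onsets, n_units) {
  n_seg <- length(seg_onsets)
  m <- matrix(0, n_seg, n_units)
  if (length(times)) {
    si <- findInterval(times, seg_onsets)
    ok <- si >= 1
    cnt <- tabulate((units[ok] - 1L) * n_seg + si[ok], n_seg * n_units)
    m[] <- cnt
  }
  m
}

# block-shuffled presentation order: each block presents every angle once
shuffle_blocks <- function(angles, n_repeats, seed) {
  with_seed(seed, unlist(lapply(seq_len(n_repeats),
                                function(b) sample(angles))))
}

orientation_net <- function(weights, delays, n_side, n_out, lif, rule,
                            lateral_w, stimulus, noise_hz, noise_w,
                            duration, seed) {
  pops <- list(
    population("retina", n_side^2, "source", stimulus = stimulus),
    population("v1", n_out, "lif", params = lif))
  conn <- data.frame(pre = rep(seq_len(n_side^2), n_out),
                     post = rep(seq_len(n_out), each = n_side^2),
                     w = weights, d = delays)
  prj <- list(
    projection("retina", "v1", conn, plastic = !is.null(rule),
               rule = rule, name = "retina->v1"))
  if (lateral_w != 0)
    prj <- c(prj, list(projection("v1", "v1",
                                  list(type = "all_to_all", self = FALSE),
                                  weight = lateral_w, delay = 1,
                                  receptor = "inh", name = "lateral")))
  if (noise_hz > 0) {
    pops <- c(pops, list(population(
      "noise", n_out, "source",
      stimulus = list(type = "poisson", rate = noise_hz, start = 0,
                      stop = duration))))
    prj <- c(prj, list(projection("noise", "v1", list(type = "one_to_one"),
                                  weight = noise_w, delay = 1,
                                  name = "noise->v1")))
  }
  network(pops, prj, seed = seed)
}

#' Orientation-selectivity experiment (BCM with lateral inhibition)
#'
#' A retina-like input layer of `n_side x n_side` Poisson pixels projects
#' all-to-all onto a small output layer under the BCM rule; the output
#' neurons inhibit each other with a fixed lateral weight.  Oriented bars
#' (total rate `total_rate_hz`, random pixel intensities) are presented in
#' block-shuffled random order.  The sliding threshold plus lateral
#' antagonism drive each output neuron to develop a receptive field for
#' one orientation; tuning curves are then measured with plasticity frozen
#' by rotating a bar in `tuning_step_deg` steps.
#'
#' @param n_side input grid side (default 16)
#' @param n_out number of output neurons (default 4)
#' @param angles training orientations (degrees)
#' @param n_repeats presentations per orientation (default 20, i.e. 80 in
#'   total)
#' @param present_ms presentation duration (ms)
#' @param total_rate_hz total input-layer rate per stimulus (Hz)
#' @param lateral_w lateral inhibitory weight (nA, default -9); set 0 to
#'   remove lateral inhibition (control)
#' @param tuning_step_deg tuning-curve angle step (degrees)
#' @param tuning_ms tuning presentation duration (ms)
#' @param bcm BCM rule parameters
#' @param init_w range of initial weights (nA)
#' @param noise_hz rate of the independent background-noise input each
#'   output neuron receives (Hz); spontaneous drive keeps suppressed
#'   neurons weakly active so they stay plastic and can re-enter the
#'   competition
#' @param noise_w weight of the noise synapses (nA)
#' @param lif LIF parameters of the output neurons
#' @param seed master seed
#' @return an `experiment_result`; metrics: `preferred_deg` per output,
#'   `is_permutation` (preferred angles are a permutation of the training
#'   angles), `tuning` (angle x neuron rate matrix, Hz), receptive fields,
#'   training response rates
#' @export
run_orientation_experiment <- function(n_side = 16, n_out = 4,
                                       angles = c(0, 45, 90, 135),
                                       n_repeats = 20, present_ms = 1000,
                                       total_rate_hz = 1000,
                                       lateral_w = -9,
                                       tuning_step_deg = 10,
                                       tuning_ms = 1000,
                                       bcm = bcm_params(delta = 2e-5,
                                                        epsilon = 1e-4,
                                                        theta_ema = 0.2,
                                                        rate_lp = 0.5,
                                                        theta0 = 20,
                                                        w_min = 1 / 12,
                                                        w_max = 5 / 3),
                                       init_w = c(1 / 3, 5 / 3),
                                       noise_hz = 300, noise_w = 5 / 6,
                                       lif = lif_params(tau_syn = 12,
                                                        v_thresh = -55,
                                                        i_offset = 2),
                                       seed = 1) {
  n_px <- n_side^2
  imgs <- lapply(seq_along(angles), function(i)
    bar_image(angles[i], seed = sub_seed(seed, paste0("bar", i)),
              size = n_side))
  rates <- lapply(imgs, bar_rates, total_rate = total_rate_hz)
  order_deg <- shuffle_blocks(angles, n_repeats,
                              sub_seed(seed, "present-order"))
  onsets <- (seq_along(order_deg) - 1) * present_ms
  rmat <- do.call(rbind, lapply(order_deg, function(a)
    as.vector(rates[[match(a, angles)]])))
  stim <- list(type = "rate_schedule", onsets = onsets,
               duration = present_ms, rates = rmat)

  n_syn <- n_px * n_out
  w_init <- with_seed(sub_seed(seed, "w-init"),
                      stats::runif(n_syn, init_w[1], init_w[2]))
  d_init <- with_seed(sub_seed(seed, "d-init"),
                      sample(1:8, n_syn, replace = TRUE))
  dur <- length(order_deg) * present_ms
  net <- orientation_net(w_init, d_init, n_side, n_out, lif,
                         rule = list(name = "bcm", params = bcm),
                         lateral_w, stim, noise_hz, noise_w, dur, seed)
  rec <- run_network(net, dur, seed = seed, snapshots = "final")
  w_fin <- rec$weights[["retina->v1"]]
  v1 <- neuron_ids(net, "v1")

  # training response rates per (presentation, neuron)
  po <- rec$spikes[rec$spikes$neuron_id %in% v1, ]
  resp <- count_by_segment(po$time_ms, po$neuron_id - v1[1] + 1L,
                           onsets, n_out) / (present_ms / 1000)

  # tuning curves with plasticity frozen, same connectivity and weights
  tune_deg <- seq(0, 179, by = tuning_step_deg)
  tune_rates <- do.call(rbind, lapply(seq_along(tune_deg), function(i)
    as.vector(bar_rates(bar_image(tune_deg[i],
                                  seed = sub_seed(seed, paste0("tb", i)),
                                  size = n_side), total_rate_hz))))
  tune_stim <- list(type = "rate_schedule",
                    onsets = (seq_along(tune_deg) - 1) * tuning_ms,
                    duration = tuning_ms, rates = tune_rates)
  pnet <- orientation_net(w_fin, d_init, n_side, n_out, lif, rule = NULL,
                          lateral_w, tune_stim, noise_hz, noise_w,
                          length(tune_deg) * tuning_ms, seed)
  prec <- run_network(pnet, length(tune_deg) * tuning_ms,
                      seed = sub_seed(seed, "tuning"), snapshots = "none")
  pv1 <- neuron_ids(pnet, "v1")
  tp <- prec$spikes[prec$spikes$neuron_id %in% pv1, ]
  tuning <- count_by_segment(tp$time_ms, tp$neuron_id - pv1[1] + 1L,
                             (seq_along(tune_deg) - 1) * tuning_ms,
                             n_out) / (tuning_ms / 1000)
  dimnames(tuning) <- list(tune_deg, NULL)
  preferred <- tune_deg[apply(tuning, 2, which.max)]
  # assign each output to the training orientation nearest its tuning peak
  # (circular distance on orientation space, period 180 degrees)
  circ <- function(a, b) pmin(abs(a - b), 180 - abs(a - b))
  assigned <- vapply(preferred, function(p)
    angles[which.min(circ(p, angles))], numeric(1))
  experiment_result("orientation", rec,
    metrics = list(preferred_deg = preferred,
                   assigned_deg = assigned,
                   is_permutation = setequal(assigned, angles) &&
                     !anyDuplicated(assigned),
                   tuning = tuning,
                   receptive_fields = lapply(seq_len(n_out), function(j)
                     matrix(w_fin[(j - 1) * n_px + seq_len(n_px)],
                            n_side, n_side)),
                   train_resp = resp, order_deg = order_deg,
                   w_final = w_fin),
    config = list(n_side = n_side, n_out = n_out, angles = angles,
                  n_repeats = n_repeats, lateral_w = lateral_w,
                  seed = seed))
}

#' Voltage-gated STDP demonstration (potentiation / depression protocols)
#'
#' A single input fires a 3-spike burst periodically onto one LIF neuron
#' through a synapse under the voltage-gated rule.  In the potentiation
#' protocol a constant bias current holds the membrane above the gating
#' threshold, so burst arrivals (with the calcium trace inside the
#' potentiation interval, charged by the neuron's own earlier responses)
#' step the weight up by `a` until it saturates and two spikes suffice to
#' fire the neuron.  In the depression protocol there is no bias, arrivals
#' see a membrane at or below the gate, and the weight steps down by `b`
#' until the neuron stops responding to the burst.
#'
#' @param mode `"potentiation"` or `"depression"`
#' @param n_spikes spikes per burst
#' @param isi_ms intra-burst interval (ms)
#' @param period_ms burst period (ms)
#' @param n_presentations number of presentations
#' @param seed master seed
#' @return an `experiment_result`; metrics: `spikes_to_fire` and
#'   `response_spikes` per presentation, `initial`, `final`, `w_final`
#' @export
run_vg_experiment <- function(mode = c("potentiation", "depression"),
                              n_spikes = 3, isi_ms = 2, period_ms = 200,
                              n_presentations = 10, seed = 1) {
  mode <- match.arg(mode)
  bias <- if (mode == "potentiation") 13 else 0
  lif <- lif_params(tau_m = 10, tau_syn = 1, t_refrac = 2, i_offset = bias)
  burst <- (seq_len(n_spikes) - 1) * isi_ms
  w0 <- calibrate_weight(lif, burst)
  prm <- vg_params(j_c = 1, tau_c = 150, theta_v = -53,
                   theta_h_down = 0.05, theta_h_up = 5,
                   theta_l_down = 0.05, theta_l_up = 5,
                   a = if (mode == "potentiation") 0.05 * w0 else 0,
                   b = if (mode == "depression") 0.1 * w0 else 0,
                   alpha = 0, beta = 0, theta_w = w0,
                   w_min = 0, w_max = 1.6 * w0)
  onsets <- (seq_len(n_presentations) - 1) * period_ms
  pops <- list(
    population("in", 1, "source",
               stimulus = list(type = "schedule",
                               times = list(as.vector(outer(burst, onsets,
                                                            "+"))))),
    population("out", 1, "lif", params = lif))
  prj <- list(projection("in", "out", list(type = "one_to_one"),
                         weight = w0, delay = 1, plastic = TRUE,
                         rule = list(name = "vg_stdp", params = prm)))
  net <- network(pops, prj, seed = seed)
  rec <- run_network(net, n_presentations * period_ms, seed = seed,
                     snapshots = "boundaries")
  out <- neuron_ids(net, "out")
  stf <- spikes_to_fire(rec, onsets, neuron_ids(net, "in"), out, delay = 1)
  po <- spike_times(rec, out)
  resp <- vapply(onsets, function(o)
    sum(po >= o & po < o + period_ms), integer(1))
  experiment_result("vg_demo", rec,
    metrics = list(spikes_to_fire = stf, response_spikes = resp,
                   initial = stf[1], final = stf[length(stf)],
                   w0 = w0, w_final = rec$weights[["in->out"]]),
    config = list(mode = mode, n_spikes = n_spikes, isi_ms = isi_ms,
                  period_ms = period_ms,
                  n_presentations = n_presentations, seed = seed))
}

#' Temporal-pattern learning with delay lines (tonotopic sweeps)
#'
#' Three tonotopically organised layers: source layer A drives two LIF
#' layers B1 and B2 one-to-one; B2 neurons additionally receive plastic
#' connections from neighbouring B1 channels with delays proportional to
#' the channel distance, plus a static one-to-one inhibitory B1->B2
#' connection.  During a frequency sweep the delayed B1 feedback from
#' channel j reaches B2 channel k exactly when the sweep itself activates
#' channel k -- but only for channel pairs consistent with the sweep
#' direction.  The voltage-gated rule (calcium coincidence window plus
#' bistable drift) potentiates exactly those synapses, so the learned
#' B1->B2 weight matrix becomes asymmetric for directional sweeps and
#' mirror-symmetric for a forked sweep.
#'
#' @param kind sweep direction: `"forward"`, `"backward"` or `"forked"`
#' @param n_channels number of frequency channels (default 16)
#' @param inter_channel_dt channel-to-channel sweep interval (ms)
#' @param repeat_gap silence between sweeps (ms)
#' @param n_repeats sweep presentations
#' @param radius largest connected channel distance
#' @param seed master seed
#' @return an `experiment_result`; metrics: `w_matrix` (pre-channel x
#'   post-channel), `asymmetry` = (sum above diagonal - sum below) / total
#'   (positive for forward, negative for backward, ~0 for forked)
#' @export
run_temporal_experiment <- function(kind = c("forward", "backward",
                                             "forked"),
                                    n_channels = 16, inter_channel_dt = 10,
                                    repeat_gap = 300, n_repeats = 40,
                                    radius = 5, seed = 1) {
  kind <- match.arg(kind)
  lif <- lif_params(tau_m = 10, tau_syn = 2, t_refrac = 2)
  drive <- calibrate_weight(lif, 0, margin = 1.3)  # one spike fires
  sw <- sweep_spikes(kind, n_channels, inter_channel_dt, repeat_gap,
                     n_repeats)
  pairs <- expand.grid(pre = seq_len(n_channels),
                       post = seq_len(n_channels))
  pairs <- pairs[pairs$pre != pairs$post &
                   abs(pairs$pre - pairs$post) <= radius, ]
  dist <- abs(pairs$pre - pairs$post)
  w_hi <- 0.2 * drive
  pairs$d <- dist * inter_channel_dt + 2
  pairs$w <- with_seed(sub_seed(seed, "w-init"),
                       stats::runif(nrow(pairs), 0.1, 0.3) * w_hi)
  # calcium window ~15 ms: feedback arriving one channel-lag (>= 22 ms)
  # after the B2 spike falls outside the potentiation interval
  prm <- vg_params(j_c = 1, tau_c = 15, theta_v = -80,
                   theta_h_down = 0.3, theta_h_up = 5,
                   theta_l_down = 0, theta_l_up = 0,  # drift-only depression
                   a = 0.06 * w_hi, b = 0,
                   alpha = 0, beta = 0.0001 * w_hi,
                   theta_w = 0.5 * w_hi, w_min = 0, w_max = w_hi)
  pops <- list(
    population("A", n_channels, "source",
               stimulus = list(type = "schedule", times = sw)),
    population("B1", n_channels, "lif", params = lif),
    population("B2", n_channels, "lif", params = lif))
  prj <- list(
    projection("A", "B1", list(type = "one_to_one"), weight = drive,
               delay = 1, name = "A->B1"),
    projection("A", "B2", list(type = "one_to_one"), weight = drive,
               delay = 1, name = "A->B2"),
    projection("B1", "B2", list(type = "one_to_one"), weight = -2,
               delay = 1, receptor = "inh", name = "B1->B2 inh"),
    projection("B1", "B2", pairs, plastic = TRUE,
               rule = list(name = "vg_stdp", params = prm),
               name = "B1->B2 plastic"))
  net <- network(pops, prj, seed = seed)
  dur <- max(unlist(sw)) + repeat_gap
  rec <- run_network(net, dur, seed = seed, snapshots = "final")
  w_fin <- rec$weights[["B1->B2 plastic"]]
  wm <- matrix(0, n_channels, n_channels)
  wm[cbind(pairs$pre, pairs$post)] <- w_fin
  upper <- sum(wm[upper.tri(wm)]); lower <- sum(wm[lower.tri(wm)])
  experiment_result("temporal", rec,
    metrics = list(w_matrix = wm,
                   asymmetry = if (upper + lower > 0)
                     (upper - lower) / (upper + lower) else 0,
                   w_final = w_fin, pairs = pairs),
    config = list(kind = kind, n_channels = n_channels,
                  inter_channel_dt = inter_channel_dt,
                  repeat_gap = repeat_gap, n_repeats = n_repeats,
                  radius = radius, seed = seed))
}

#' STDP teacher-pairing experiment
#'
#' A stimulus population and a target population are each driven by their
#' own burst source (one-to-one), with 50% random connectivity from
#' stimulus to target under STDP.  During the pairing phase the target
#' teacher fires `lag_ms` after the stimulus teacher, so stimulus spikes
#' systematically precede target spikes and the plastic synapses
#' potentiate; in the test phase the teacher is removed and the stimulus
#' alone drives the target.
#'
#' @param n_per_pop neurons per population
#' @param lag_ms teacher lag (ms, default 10)
#' @param burst_rate_hz,burst_ms teacher burst parameters
#' @param noise_hz independent background noise rate (Hz)
#' @param seed master seed
#' @return an `experiment_result`; metrics: target spike counts in the
#'   stimulus-only, pairing and test phases, and mean plastic weight
#'   before/after
#' @export
run_teacher_experiment <- function(n_per_pop = 10, lag_ms = 10,
                                   burst_rate_hz = 350, burst_ms = 20,
                                   noise_hz = 2, seed = 1) {
  lif <- lif_params()
  # one burst (~7 spikes at 350 Hz over 20 ms) through one strong synapse
  # must drive a neuron; through the weak plastic ones it must not
  drive <- calibrate_weight(lif, seq(0, burst_ms - 1, by = 3), margin = 1.2)
  phase1 <- seq(100, 1300, by = 200)
  phase2 <- seq(1500, 2900, by = 200)
  phase3 <- seq(3500, 4300, by = 200)
  tp <- teacher_protocol(c(phase1, phase2, phase3), lag_ms,
                         burst_rate_hz, burst_ms, n_stim = n_per_pop,
                         seed = sub_seed(seed, "stim-bursts"))
  # the target teacher is only active during the pairing phase
  tt <- teacher_protocol(phase2, lag_ms, burst_rate_hz, burst_ms,
                         n_stim = n_per_pop, n_target = n_per_pop,
                         seed = sub_seed(seed, "teach-bursts"))
  w0 <- 0.05 * drive
  prm <- stdp_params(a_plus = 0.12 * drive, a_minus = 0.015 * drive,
                     tau_plus = 20, tau_minus = 20,
                     w_min = 0, w_max = drive)
  pops <- list(
    population("stim_src", n_per_pop, "source",
               stimulus = list(type = "schedule", times = tp$stimulus)),
    population("teach_src", n_per_pop, "source",
               stimulus = list(type = "schedule",
                               times = lapply(tt$target, `+`, 0))),
    population("noise_s", n_per_pop, "source",
               stimulus = list(type = "poisson", rate = noise_hz,
                               start = 0, stop = 4500)),
    population("noise_t", n_per_pop, "source",
               stimulus = list(type = "poisson", rate = noise_hz,
                               start = 0, stop = 4500)),
    population("stimulus", n_per_pop, "lif", params = lif),
    population("target", n_per_pop, "lif", params = lif))
  prj <- list(
    # relays fire 2-3 spikes per 20 ms burst at 1.5x the one-spike drive
    projection("stim_src", "stimulus", list(type = "one_to_one"),
               weight = 1.5 * drive, delay = 1),
    projection("teach_src", "target", list(type = "one_to_one"),
               weight = 1.5 * drive, delay = 1),
    projection("noise_s", "stimulus", list(type = "one_to_one"),
               weight = 0.3 * drive, delay = 1),
    projection("noise_t", "target", list(type = "one_to_one"),
               weight = 0.3 * drive, delay = 1),
    projection("stimulus", "target", list(type = "bernoulli", p = 0.5),
               weight = w0, delay = 1, plastic = TRUE,
               rule = list(name = "stdp_trace", params = prm),
               name = "stimulus->target"))
  net <- network(pops, prj, seed = seed)
  w_init <- net$projections[[5]]$w
  rec <- run_network(net, 4500, seed = seed, snapshots = "final")
  tgt <- neuron_ids(net, "target")
  po <- spike_times(rec, tgt)
  cnt <- function(a, b) sum(po >= a & po < b)
  experiment_result("teacher_stdp", rec,
    metrics = list(target_spikes_phase1 = cnt(0, 1400),
                   target_spikes_pairing = cnt(1500, 3000),
                   target_spikes_test = cnt(3500, 4500),
                   w_mean_initial = mean(w_init),
                   w_mean_final = mean(rec$weights[["stimulus->target"]])),
    config = list(n_per_pop = n_per_pop, lag_ms = lag_ms, seed = seed))
}

#' BCM teacher-pairing experiment
#'
#' A Poisson stimulus population drives a target population through weak
#' plastic synapses under BCM.  When a strong teacher input forces the
#' target to fire above its sliding threshold while the stimulus is
#' active, the stimulus synapses potentiate; after the teacher is removed
#' the stimulus alone drives the target.
#'
#' @param n_per_pop neurons per population
#' @param stim_rate_hz stimulus Poisson rate (Hz)
#' @param teach_rate_hz teacher Poisson rate during the pairing phase (Hz)
#' @param seed master seed
#' @return an `experiment_result`; metrics: target spike counts per phase
#'   and mean plastic weight before/after
#' @export
run_bcm_teacher_experiment <- function(n_per_pop = 10, stim_rate_hz = 50,
                                       teach_rate_hz = 100, seed = 1) {
  lif <- lif_params()
  drive <- calibrate_weight(lif, c(0, 10), margin = 1.2)
  w0 <- 0.05 * drive
  prm <- bcm_params(delta = 2e-5, epsilon = 0, theta_ema = 0.1,
                    rate_lp = 0.8, w_min = 0, w_max = 0.6 * drive)
  pops <- list(
    population("stim_src", n_per_pop, "source",
               stimulus = list(type = "poisson", rate = stim_rate_hz,
                               start = 0, stop = 1800)),
    population("teach_src", n_per_pop, "source",
               stimulus = list(type = "poisson", rate = teach_rate_hz,
                               start = 600, stop = 1200)),
    population("target", n_per_pop, "lif", params = lif))
  prj <- list(
    projection("teach_src", "target", list(type = "one_to_one"),
               weight = drive, delay = 1),
    projection("stim_src", "target", list(type = "all_to_all"),
               weight = w0, delay = 1, plastic = TRUE,
               rule = list(name = "bcm", params = prm),
               name = "stim->target"))
  net <- network(pops, prj, seed = seed)
  w_init <- net$projections[[2]]$w
  rec <- run_network(net, 1800, seed = seed, snapshots = "final")
  po <- spike_times(rec, neuron_ids(net, "target"))
  cnt <- function(a, b) sum(po >= a & po < b)
  experiment_result("bcm_teacher", rec,
    metrics = list(target_spikes_before = cnt(0, 600),
                   target_spikes_pairing = cnt(600, 1200),
                   target_spikes_after = cnt(1200, 1800),
                   w_mean_initial = mean(w_init),
                   w_mean_final = mean(rec$weights[["stim->target"]])),
    config = list(n_per_pop = n_per_pop, stim_rate_hz = stim_rate_hz,
                  teach_rate_hz = teach_rate_hz, seed = seed))
}

#' Run a named experiment
#'
#' Dispatch table used by the command line interface.
#'
#' @param name one of `"latency"`, `"burst_stdp"`, `"teacher_stdp"`,
#'   `"song"`, `"bcm_teacher"`, `"orientation"`, `"vg_demo"`,
#'   `"temporal"`
#' @param seed master seed
#' @param ... overrides forwarded to the experiment function
#' @return an `experiment_result`
#' @export
run_experiment <- function(name, seed = 1, ...) {
  switch(name,
    latency = run_latency_experiment(seed = seed, ...),
    burst_stdp = run_burst_experiment(seed = seed, ...),
    teacher_stdp = run_teacher_experiment(seed = seed, ...),
    song = run_song_experiment(seed = seed, ...),
    bcm_teacher = run_bcm_teacher_experiment(seed = seed, ...),
    orientation = run_orientation_experiment(seed = seed, ...),
    vg_demo = run_vg_experiment(seed = seed, ...),
    temporal = run_temporal_experiment(seed = seed, ...),
    stop("unknown experiment: ", name))
}
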