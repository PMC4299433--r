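# Network description: populations, projections, synaptic rows and input
# ring buffers.  Projections are declared (connectivity pattern + weight and
# delay distributions) and realised into explicit synapse tables when the
# network is built, using named RNG sub-streams so connectivity, initial
# weights and stimuli can be varied independently from one master seed.

#' Create a synaptic row
#'
#' A synaptic row holds every synapse sharing one presynaptic neuron -- the
#' unit of storage and of batched weight update.  Entries are kept sorted by
#' postsynaptic index; delays are integer milliseconds, minimum 1 (delays
#' are reintroduced at the postsynaptic end).
#'
#' @param pre_id presynaptic neuron index
#' @param post postsynaptic indices
#' @param w synaptic weights (nA), recycled
#' @param d integer delays (ms, >= 1), recycled
#' @param plastic logical flag per entry, recycled
#' @return a `synaptic_row` object
#' @export
synaptic_row <- function(pre_id, post, w = 1, d = 1, plastic = FALSE) {
  n <- length(post)
  w <- rep_len(w, n); d <- as.integer(rep_len(d, n))
  plastic <- rep_len(plastic, n)
  if (any(d < 1)) stop("delays must be >= 1 ms")
  o <- order(post)
  structure(list(pre_id = pre_id, post = post[o], w = w[o], d = d[o],
                 plastic = plastic[o]),
            class = "synaptic_row")
}

#' Create a per-neuron input ring buffer
#'
#' A circular array of per-millisecond accumulated synaptic weight, one lane
#' per synapse type (excitatory / inhibitory).  The slot consumed at time t
#' is zeroed after use; the span must exceed the largest delay.
#'
#' @param n_neurons number of target neurons
#' @param span buffer span (ms)
#' @return an `input_ring_buffer` object
#' @export
input_ring_buffer <- function(n_neurons, span) {
  stopifnot(span >= 2)
  structure(list(e = matrix(0, span, n_neurons),
                 i = matrix(0, span, n_neurons), span = span),
            class = "input_ring_buffer")
}

#' Deliver one presynaptic spike through a synaptic row
#'
#' Adds each entry's weight into the target neuron's buffer slot `t + d`
#' (the delay is applied here, at the postsynaptic end).  Simultaneous
#' deliveries into one slot sum linearly.
#'
#' @param row a [synaptic_row()]
#' @param buffers an [input_ring_buffer()]
#' @param t spike time (ms)
#' @param lane `"exc"` or `"inh"`
#' @return the updated buffers
#' @examples
#' b <- input_ring_buffer(4, span = 16)
#' b <- deliver_spike(synaptic_row(1, post = 3, w = 2, d = 5), b, t = 10)
#' b$e[(15 %% 16) + 1, 3]
#' @export
deliver_spike <- function(row, buffers, t, lane = c("exc", "inh")) {
  lane <- match.arg(lane)
  if (length(row$post) == 0) return(buffers)
  if (any(row$d >= buffers$span))
    stop("delay exceeds ring-buffer span: configuration error")
  slot <- ((t + row$d) %% buffers$span) + 1L
  m <- if (lane == "exc") "e" else "i"
  for (k in seq_along(row$post))
    buffers[[m]][slot[k], row$post[k]] <-
      buffers[[m]][slot[k], row$post[k]] + row$w[k]
  buffers
}

# read-and-zero the slot for time t; returns list(e, i, buffers)
consume_inputs <- function(buffers, t) {
  slot <- (t %% buffers$span) + 1L
  e <- buffers$e[slot, ]; i <- buffers$i[slot, ]
  buffers$e[slot, ] <- 0; buffers$i[slot, ] <- 0
  list(e = e, i = i, buffers = buffers)
}

#' Declare a neuron population
#'
#' @param name population name (unique within a network)
#' @param n number of neurons
#' @param model `"lif"` for integrate-and-fire neurons or `"source"` for
#'   spike sources driven by a stimulus specification
#' @param params a [lif_params()] object (LIF populations)
#' @param stimulus for source populations, one of
#'   `list(type = "poisson", rate =, start =, stop =)`,
#'   `list(type = "schedule", times = <list of per-neuron spike vectors>)`, or
#'   `list(type = "rate_schedule", onsets =, duration =, rates = <matrix
#'   n_segments x n>)` for piecewise-constant per-neuron rates
#' @return a `population` object
#' @export
population <- function(name, n, model = c("lif", "source"),
                       params = lif_params(), stimulus = NULL) {
  model <- match.arg(model)
  stopifnot(is.character(name), n >= 1)
  if (model == "source" && is.null(stimulus))
    stop(sprintf("source population '%s' needs a stimulus", name))
  if (model == "lif" && !inherits(params, "lif_params"))
    stop(sprintf("population '%s': params must be lif_params", name))
  structure(list(name = name, n = as.integer(n), model = model,
                 params = params, stimulus = stimulus),
            class = "population")
}

#' Declare a projection between two populations
#'
#' Connectivity is either a pattern (`one_to_one`, `all_to_all`, or
#' `bernoulli` with probability `p`) realised when the network is built, or
#' an explicit synapse table `data.frame(pre, post[, w, d])` with 1-based
#' local indices.  Weights and delays may be constants, per-synapse vectors
#' (explicit tables), or distributions
#' `list(type = "uniform", min =, max =)` /
#' `list(type = "uniform_int", min =, max =)`.
#'
#' @param source,target population names
#' @param connectivity connectivity pattern, e.g. `list(type =
#'   "all_to_all", self = FALSE)`, `list(type = "bernoulli", p = 0.5)`,
#'   `list(type = "one_to_one")`, or an explicit `data.frame`
#' @param weight weight specification (nA); inhibitory projections use
#'   negative weights
#' @param delay delay specification (integer ms, >= 1)
#' @param receptor `"exc"` or `"inh"` (which ring-buffer lane is used)
#' @param plastic logical; plastic projections need a `rule`
#' @param rule plasticity rule: `list(name = <"stdp_trace" | "bcm" |
#'   "vg_stdp">, params = <matching params object>)`
#' @param name optional projection name (defaults to "source->target")
#' @return a `projection` object
#' @export
projection <- function(source, target,
                       connectivity = list(type = "all_to_all"),
                       weight = 1, delay = 1,
                       receptor = c("exc", "inh"),
                       plastic = FALSE, rule = NULL, name = NULL) {
  receptor <- match.arg(receptor)
  if (plastic) {
    if (is.null(rule) || is.null(rule$name) ||
        !rule$name %in% c("stdp_trace", "bcm", "vg_stdp"))
      stop(sprintf("projection %s->%s: unknown or missing plasticity rule",
                   source, target))
  }
  if (is.null(name)) name <- paste0(source, "->", target)
  structure(list(name = name, source = source, target = target,
                 connectivity = connectivity, weight = weight,
                 delay = delay, receptor = receptor, plastic = plastic,
                 rule = rule),
            class = "projection")
}

realize_pairs <- function(conn, n_pre, n_post, proj_name) {
  if (is.data.frame(conn)) {
    if (any(conn$pre < 1 | conn$pre > n_pre) ||
        any(conn$post < 1 | conn$post > n_post))
      stop(sprintf("projection %s: synapse table indices out of range",
                   proj_name))
    return(conn[c("pre", "post")])
  }
  switch(conn$type,
    one_to_one = {
      if (n_pre != n_post)
        stop(sprintf("projection %s: one_to_one needs equal sizes",
                     proj_name))
      data.frame(pre = seq_len(n_pre), post = seq_len(n_post))
    },
    all_to_all = {
      g <- expand.grid(pre = seq_len(n_pre), post = seq_len(n_post))
      if (isFALSE(conn$self %||% TRUE)) g <- g[g$pre != g$post, ]
      g
    },
    bernoulli = {
      p <- conn$p
      if (is.null(p) || p < 0 || p > 1)
        stop(sprintf("projection %s: bernoulli needs p in [0, 1]",
                     proj_name))
      g <- expand.grid(pre = seq_len(n_pre), post = seq_len(n_post))
      g[stats::runif(nrow(g)) < p, ]
    },
    stop(sprintf("projection %s: unknown connectivity type '%s'",
                 proj_name, conn$type)))
}

realize_values <- function(spec, n, integer = FALSE) {
  v <- if (is.list(spec)) {
    switch(spec$type,
      uniform = stats::runif(n, spec$min, spec$max),
      uniform_int = sample(seq(spec$min, spec$max), n, replace = TRUE),
      stop(sprintf("unknown value distribution '%s'", spec$type)))
  } else rep_len(spec, n)
  if (integer) as.integer(round(v)) else v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a simulatable network from populations and projections
#'
#' Validates the description (referenced populations exist, delays are
#' integer and >= 1, probabilities are valid) and realises every projection
#' into an explicit synapse table.  Connectivity, weight and delay draws use
#' named sub-streams derived from `seed`.
#'
#' @param populations list of [population()] objects
#' @param projections list of [projection()] objects
#' @param seed integer seed for connectivity / weight / delay realisation
#' @param window_ms plasticity window span (ms), default 128
#' @param bin_ms spike-history bitmap resolution (ms), default 2
#' @return a `network` object with realised projections
#' @export
network <- function(populations, projections = list(), seed = 1,
                    window_ms = 128, bin_ms = 2) {
  errs <- character(0)
  pnames <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(pnames))
    errs <- c(errs, "duplicate population names")
  sizes <- stats::setNames(vapply(populations, `[[`, 0L, "n"), pnames)
  offsets <- stats::setNames(c(0L, cumsum(sizes))[seq_along(sizes)], pnames)
  for (pr in projections) {
    for (side in c("source", "target"))
      if (!pr[[side]] %in% pnames)
        errs <- c(errs, sprintf(
          "projection %s references unknown population '%s'",
          pr$name, pr[[side]]))
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))

  realized <- vector("list", length(projections))
  for (k in seq_along(projections)) {
    pr <- projections[[k]]
    n_pre <- sizes[[pr$source]]; n_post <- sizes[[pr$target]]
    pairs <- with_seed(sub_seed(seed, paste0("conn:", k, pr$name)),
                       realize_pairs(pr$connectivity, n_pre, n_post,
                                     pr$name))
    S <- nrow(pairs)
    expl <- is.data.frame(pr$connectivity)
    w <- if (expl && !is.null(pr$connectivity$w)) pr$connectivity$w else
      with_seed(sub_seed(seed, paste0("w:", k, pr$name)),
                realize_values(pr$weight, S))
    d <- if (expl && !is.null(pr$connectivity$d))
      as.integer(pr$connectivity$d) else
      with_seed(sub_seed(seed, paste0("d:", k, pr$name)),
                realize_values(pr$delay, S, integer = TRUE))
    if (S > 0 && any(d < 1))
      errs <- c(errs, sprintf("projection %s: delays must be >= 1 ms",
                              pr$name))
    pr$pre_local <- pairs$pre
    pr$post_local <- pairs$post
    pr$pre <- pairs$pre + offsets[[pr$source]]
    pr$post <- pairs$post + offsets[[pr$target]]
    pr$w <- as.numeric(w)
    pr$d <- d
    pr$n_pre <- n_pre
    pr$n_post <- n_post
    pr$src_offset <- offsets[[pr$source]]
    realized[[k]] <- pr
  }
  if (length(errs)) stop(paste(errs, collapse = "\n"))

  structure(list(populations = populations, projections = realized,
                 sizes = sizes, offsets = offsets,
                 n_neurons = sum(sizes), seed = seed,
                 window_ms = window_ms, bin_ms = bin_ms),
            class = "network")
}

#' Global neuron indices of a population
#'
#' @param net a [network()] object
#' @param name population name
#' @return integer vector of global (1-based) neuron ids
#' @export
neuron_ids <- function(net, name) {
  if (!name %in% names(net$sizes)) stop("unknown population: ", name)
  net$offsets[[name]] + seq_len(net$sizes[[name]])
}
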