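# Synthetic stimulus generators.  All generators are pure functions of
# their arguments and an explicit seed: the same call reproduces the same
# trains bit for bit.  Spike times are integer milliseconds, matching the
# 1 ms engine resolution.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# derive a named sub-stream seed from one master seed (kept below 2^31)
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Bernoulli(p)-per-millisecond spike placement over [start, stop) for one
# source, sampled as binomial count + uniform placement (the distribution
# of a per-slot Bernoulli train, without materialising one draw per slot).
bernoulli_slots <- function(p, start, stop) {
  n <- stop - start
  if (n <= 0 || p <= 0) return(numeric(0))
  k <- stats::rbinom(1, n, p)
  if (k == 0) return(numeric(0))
  sort(sample.int(n, k)) - 1 + start
}

#' Generate independent Poisson spike trains
#'
#' Each source emits spikes independently with per-millisecond probability
#' `rate / 1000` over `[start, stop)` (rates above 1000 Hz are capped at one
#' spike per millisecond, with a warning).
#'
#' @param rate firing rate (Hz), >= 0
#' @param start,stop train extent (ms), `start < stop`
#' @param n_sources number of independent sources
#' @param seed optional integer seed; the global RNG state is restored
#' @return a list of `n_sources` numeric vectors of spike times (ms)
#' @examples
#' poisson_train(rate = 0, start = 0, stop = 100)
#' @export
poisson_train <- function(rate, start = 0, stop = 1000, n_sources = 1,
                          seed = NULL) {
  stopifnot(rate >= 0, start < stop, n_sources >= 1)
  p <- rate / 1000
  if (p > 1) {
    warning("rate exceeds 1000 Hz; capping at one spike per millisecond")
    p <- 1
  }
  with_seed(seed,
            lapply(seq_len(n_sources),
                   function(i) bernoulli_slots(p, start, stop)))
}

#' Build a paired stimulus/teacher burst protocol
#'
#' Produces two burst schedules: the stimulus sources emit a
#' high-frequency Poisson burst at every onset in `stim_onsets`, and the
#' target (teacher) sources emit the same bursts shifted by `target_lag`
#' ms, so that the taught population spikes after the stimulus and timing-
#' based rules potentiate the stimulus-to-target synapses.
#'
#' @param stim_onsets burst onset times (ms)
#' @param target_lag teacher delay (ms), >= 0
#' @param burst_rate in-burst Poisson rate (Hz), default 350
#' @param burst_ms burst duration (ms), default 20
#' @param n_stim,n_target number of independent stimulus / teacher sources
#' @param seed optional integer seed
#' @return a list with `stimulus` and `target`, each a list of per-source
#'   spike-time vectors, plus the two onset vectors
#' @export
teacher_protocol <- function(stim_onsets, target_lag, burst_rate = 350,
                             burst_ms = 20, n_stim = 1, n_target = 1,
                             seed = NULL) {
  stopifnot(target_lag >= 0)
  gen <- function(onsets, n, p) {
    lapply(seq_len(n), function(i)
      unlist(lapply(onsets, function(o)
        bernoulli_slots(p, o, o + burst_ms)), use.names = FALSE))
  }
  p <- min(burst_rate / 1000, 1)
  with_seed(seed, {
    list(stimulus = gen(stim_onsets, n_stim, p),
         target = gen(stim_onsets + target_lag, n_target, p),
         stimulus_onsets = stim_onsets,
         target_onsets = stim_onsets + target_lag)
  })
}

#' Rasterise an oriented-bar stimulus image
#'
#' Draws a bar of the given orientation on a square intensity grid.  Pixel
#' centres use integer coordinates; a pixel is on the bar when its centre,
#' rotated into the bar frame, falls inside the centred
#' `length x thickness` box (nearest-pixel rounding at oblique angles, so
#' the box is symmetric and a 180-degree rotation keeps the pixel set).
#' On-bar intensities are drawn uniformly from `[0.8, 1.0]`; off-bar
#' pixels are 0.
#'
#' @param angle bar orientation (degrees, counter-clockwise from
#'   horizontal)
#' @param seed optional integer seed for the pixel intensities
#' @param size grid side (pixels), default 16
#' @param thickness bar thickness (pixels), default 3
#' @param length bar length (pixels), default 12
#' @return a `bar_stimulus` object with fields `image` (size x size
#'   matrix, rows = y), `angle`, `thickness`, `length`
#' @export
bar_image <- function(angle, seed = NULL, size = 16, thickness = 3,
                      length = 12) {
  half <- size / 2
  xs <- seq_len(size) - half       # integer centres -7..8 for size 16
  grid_x <- matrix(xs, size, size, byrow = TRUE)
  grid_y <- matrix(xs, size, size)
  th <- angle * pi / 180
  u <- grid_x * cos(th) + grid_y * sin(th)    # along the bar
  v <- -grid_x * sin(th) + grid_y * cos(th)   # across the bar
  eps <- 1e-9  # FP guard so exact box faces keep their pixels at 90/180 deg
  on <- (abs(u) <= length / 2 + eps) & (abs(v) <= thickness / 2 + eps)
  img <- matrix(0, size, size)
  img[on] <- with_seed(seed, stats::runif(sum(on), 0.8, 1.0))
  structure(list(image = img, angle = angle, thickness = thickness,
                 length = length),
            class = "bar_stimulus")
}

#' Convert an intensity image to per-pixel Poisson rates
#'
#' Rates are proportional to pixel intensity and scaled so they sum to
#' `total_rate` (an all-zero image yields all-zero rates).
#'
#' @param image a [bar_image()] object or a numeric intensity matrix
#' @param total_rate total firing rate summed over pixels (Hz)
#' @return a matrix of per-pixel rates (Hz) with the shape of the image
#' @export
bar_rates <- function(image, total_rate = 1000) {
  img <- if (inherits(image, "bar_stimulus")) image$image else image
  s <- sum(img)
  if (s == 0) return(img * 0)
  img / s * total_rate
}

#' Generate a tonotopic frequency-sweep spike pattern
#'
#' One spike per channel per repetition.  `forward` activates channels in
#' order with `inter_channel_dt` between neighbours, `backward` reverses
#' the order, and `forked` starts at the middle channel and proceeds
#' outward in both directions simultaneously.
#'
#' @param kind one of `"forward"`, `"backward"`, `"forked"`
#' @param n_channels number of frequency channels, >= 3
#' @param inter_channel_dt time between neighbouring channels (ms)
#' @param repeat_gap silent gap after each sweep before the next one (ms)
#' @param n_repeats number of sweep presentations
#' @return a list of per-channel spike-time vectors (ms); attribute
#'   `onsets` holds the sweep onset times
#' @examples
#' sweep_spikes("forked", n_channels = 5, inter_channel_dt = 10)
#' @export
sweep_spikes <- function(kind = c("forward", "backward", "forked"),
                         n_channels, inter_channel_dt = 10,
                         repeat_gap = 200, n_repeats = 1) {
  kind <- match.arg(kind)
  stopifnot(n_channels >= 3, n_repeats >= 1)
  k <- seq_len(n_channels)
  offs <- switch(kind,
    forward = (k - 1) * inter_channel_dt,
    backward = (n_channels - k) * inter_channel_dt,
    forked = abs(k - floor((n_channels + 1) / 2)) * inter_channel_dt)
  span <- max(offs)
  period <- span + repeat_gap
  onsets <- (seq_len(n_repeats) - 1) * period
  out <- lapply(k, function(ch) onsets + offs[ch])
  attr(out, "onsets") <- onsets
  out
}
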