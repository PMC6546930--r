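#' Stimulus containers
#'
#' `image_stimulus()` wraps a 2-D grayscale intensity array with values in
#' `[0, 255]` and a presentation duration (default 300 ms).
#' `channel_stimulus()` wraps a channels-by-steps matrix of instantaneous
#' firing probabilities in `[0, 1]` at a fixed step (default 0.5 ms), the
#' format produced by cochlear front-ends (one row per frequency channel).
#'
#' @param pixels numeric matrix, intensities in `[0, 255]`.
#' @param T presentation duration, ms.
#' @return an object of class `image_stimulus` / `channel_stimulus`.
#' @export
image_stimulus <- function(pixels, T = 300) {
  stopifnot(is.matrix(pixels), T > 0)
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 255))
    stop_liquidens("pixel intensities must lie in [0, 255]", "invalid_stimulus")
  structure(list(pixels = pixels, T = T), class = "image_stimulus")
}

#' @rdname image_stimulus
#' @param probabilities matrix (n_channels x n_steps) of per-step firing
#'   probabilities in `[0, 1]`.
#' @param dt step, ms.
#' @export
channel_stimulus <- function(probabilities, dt = 0.5) {
  stopifnot(is.matrix(probabilities), dt > 0)
  if (any(!is.finite(probabilities)) || any(probabilities < 0) ||
      any(probabilities > 1))
    stop_liquidens("channel probabilities must lie in [0, 1]",
                   "invalid_stimulus")
  structure(list(probabilities = probabilities, dt = dt),
            class = "channel_stimulus")
}

#' Poisson rate encoding of an image
#'
#' Maps pixel `i` to a Poisson spike train whose mean rate is proportional to
#' its intensity: `r_i = (I_i / 255) * r_max`. Generation is per-step
#' Bernoulli at the simulator's clock: pixel `i` fires in a step of length
#' `dt` with probability `(I_i / 255) * r_max * dt`. A maximum-intensity
#' pixel at the default `r_max` fires at 63.75 Hz; a zero pixel never fires.
#' Spike times are stamped at step ends. Input lines are ordered
#' column-major over the pixel array.
#'
#' @param img an [image_stimulus()] (or a plain matrix, which is wrapped).
#' @param r_max rate of a 255-intensity pixel, Hz (default 63.75).
#' @param T presentation duration, ms.
#' @param dt step, ms.
#' @param seed integer seed; generation is deterministic per seed.
#' @return a [spike_record()] with one line per pixel.
#' @export
encode_image_poisson <- function(img, r_max = 63.75,
                                 T = if (inherits(img, "image_stimulus"))
                                   img$T else 300,
                                 dt = 0.5, seed = NULL) {
  if (!inherits(img, "image_stimulus")) img <- image_stimulus(img, T = T)
  p_max <- r_max * dt / 1000  # rate in Hz, step in ms
  if (p_max > 1)
    stop_liquidens("r_max * dt exceeds one spike per step", "rate_overflow")
  n_steps <- as.integer(round(T / dt))
  p <- as.vector(img$pixels) / 255 * p_max
  n_pix <- length(p)
  with_seed(seed, {
    draws <- matrix(runif(n_pix * n_steps), n_pix, n_steps) < p
    idx <- which(draws, arr.ind = TRUE)
    spike_record(idx[, 1], idx[, 2] * dt, duration = T, n_neurons = n_pix)
  })
}

#' Probability-matrix encoding of a multichannel stimulus
#'
#' Channel `i` emits a spike at step `j` with probability
#' `probabilities[i, j]` (at most one spike per channel per step). This is the
#' encoding used for cochleagram-like inputs, where normalized channel
#' intensities serve directly as instantaneous firing probabilities.
#'
#' @param stim a [channel_stimulus()].
#' @param seed integer seed.
#' @return a [spike_record()] with one line per channel.
#' @export
encode_channels <- function(stim, seed = NULL) {
  stopifnot(inherits(stim, "channel_stimulus"))
  pr <- stim$probabilities
  n_steps <- ncol(pr)
  with_seed(seed, {
    draws <- matrix(runif(length(pr)), nrow(pr), n_steps) < pr
    idx <- which(draws, arr.ind = TRUE)
    spike_record(idx[, 1], idx[, 2] * stim$dt,
                 duration = n_steps * stim$dt, n_neurons = nrow(pr))
  })
}

#' Parameters of the filtered spike-train distance
#'
#' @param tau_in Gaussian kernel width, ms (default 5).
#' @param grid_dt discretization step of the filtered signals, ms.
#' @param T evaluation window, ms; `NULL` uses the records' duration.
#' @return an object of class `distance_params`.
#' @export
distance_params <- function(tau_in = 5, grid_dt = 0.5, T = NULL) {
  stopifnot(tau_in > 0, grid_dt > 0, is.null(T) || T > 0)
  structure(list(tau_in = tau_in, grid_dt = grid_dt, T = T),
            class = "distance_params")
}

# Gaussian-filtered signal of one multichannel train on a time grid:
# rows = channels, cols = grid points. Kernel exp(-(t/tau)^2), two-sided.
filter_train <- function(rec, grid, tau_in) {
  f <- matrix(0, rec$n_neurons, length(grid))
  if (length(rec$time)) {
    by_ch <- split(rec$time, factor(rec$neuron, levels = seq_len(rec$n_neurons)))
    for (c in seq_len(rec$n_neurons)) {
      ts <- by_ch[[c]]
      if (length(ts))
        f[c, ] <- colSums(exp(-((outer(ts, grid, "-")) / tau_in)^2))
    }
  }
  f
}

#' Distance between two spike trains under Gaussian filtering
#'
#' Both trains are convolved with the Gaussian kernel
#' \eqn{e^{-(t/\tau_{in})^2}} on a regular grid of step `grid_dt`, and the
#' distance is the Euclidean norm of the difference over the window,
#' multiplied by `sqrt(grid_dt)` so that the value approximates the
#' continuous L2 norm and is stable under grid refinement.
#'
#' @param u,v [spike_record()]s with equal duration and channel count.
#' @param params a [distance_params()].
#' @return a non-negative scalar; a pseudo-metric on filtered trains.
#' @export
spike_distance <- function(u, v, params = distance_params()) {
  stopifnot(inherits(u, "spike_record"), inherits(v, "spike_record"))
  if (u$duration != v$duration || u$n_neurons != v$n_neurons)
    stop_liquidens("spike trains have mismatched duration or channel count",
                   "incompatible_stimuli")
  T <- if (is.null(params$T)) u$duration else params$T
  grid <- seq(0, T, by = params$grid_dt)
  fu <- filter_train(u, grid, params$tau_in)
  fv <- filter_train(v, grid, params$tau_in)
  sqrt(params$grid_dt * sum((fu - fv)^2))
}

#' Jitter the spike times of a train
#'
#' Shifts every spike time by an independent Gaussian(0, `sigma`) delay,
#' clips to `[0, duration]` and re-sorts. Channel assignment and spike count
#' are preserved. Used to fabricate same-class ("jittered") replicas of an
#' input for generalization measurements.
#'
#' @param u a [spike_record()].
#' @param sigma jitter standard deviation, ms (default 4; >= 0).
#' @param seed integer seed.
#' @return a [spike_record()] with the same spike count.
#' @export
jitter_train <- function(u, sigma = 4, seed = NULL) {
  stopifnot(inherits(u, "spike_record"), sigma >= 0)
  if (sigma == 0 || !length(u$time)) return(u)
  with_seed(seed, {
    t_new <- pmin(pmax(u$time + rnorm(length(u$time), 0, sigma), 0),
                  u$duration)
    spike_record(u$neuron, t_new, duration = u$duration,
                 n_neurons = u$n_neurons)
  })
}
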