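#' Suite of spike-train pairs with controlled inter-train distance
#'
#' Generates `n_pairs` pairs `(u, v)` of multichannel Poisson spike trains
#' whose filtered distance ([spike_distance()]) spans a range: the partner
#' `v` of each pair is obtained from `u` by re-drawing a fraction of its
#' spike times uniformly over the window, with the fraction ramping from 0
#' (identical trains, distance 0) to 1 across the suite. Pairs are grouped
#' into `distance_bins` bins by fraction; the suite stores each pair's
#' measured distance and asserts that bin-mean distances are non-decreasing,
#' retrying with a derived sub-seed a bounded number of times before raising
#' a generation failure.
#'
#' @param n_pairs number of pairs (>= 1).
#' @param duration window, ms.
#' @param channels input lines per train.
#' @param rate base Poisson rate per channel, Hz.
#' @param distance_bins number of distance bins.
#' @param dt encoder step, ms.
#' @param seed integer seed; the suite is bitwise reproducible per seed.
#' @param max_retries bound on re-generation attempts.
#' @return an object of class `spike_pair_suite`: `pairs` (list of
#'   `list(u, v, fraction, distance, bin)`), plus the generation parameters.
#' @export
gen_spike_pair_suite <- function(n_pairs = 20, duration = 300, channels = 4,
                                 rate = 40, distance_bins = 4, dt = 0.5,
                                 seed = 1, max_retries = 5) {
  stopifnot(is_count(n_pairs, 1L), duration > 0, is_count(channels, 1L),
            rate >= 0, is_count(distance_bins, 1L))
  n_steps <- as.integer(round(duration / dt))
  p <- rate * dt / 1000
  fractions <- if (n_pairs == 1) 0 else (seq_len(n_pairs) - 1) / (n_pairs - 1)
  bins <- if (n_pairs == 1 || distance_bins == 1) rep(1L, n_pairs) else
    cut(fractions, breaks = distance_bins, labels = FALSE,
        include.lowest = TRUE)
  dp <- distance_params(tau_in = 5, grid_dt = dt)

  for (attempt in 0:max_retries) {
    pairs <- with_seed(derive_seed(seed, attempt * 1000L), {
      lapply(seq_len(n_pairs), function(i) {
        stim <- channel_stimulus(matrix(p, channels, n_steps), dt = dt)
        u <- encode_channels(stim)
        v <- u
        if (fractions[i] > 0 && length(u$time)) {
          redraw <- runif(length(u$time)) < fractions[i]
          t_new <- u$time
          t_new[redraw] <- sample.int(n_steps, sum(redraw),
                                      replace = TRUE) * dt
          v <- spike_record(u$neuron, t_new, duration = duration,
                            n_neurons = channels)
        }
        list(u = u, v = v, fraction = fractions[i],
             distance = spike_distance(u, v, dp), bin = bins[i])
      })
    })
    bin_means <- tapply(vapply(pairs, function(x) x$distance, numeric(1)),
                        factor(vapply(pairs, function(x) x$bin, integer(1)),
                               levels = seq_len(distance_bins)), mean)
    if (!is.unsorted(bin_means, na.rm = TRUE)) {
      return(structure(list(pairs = pairs, duration = duration,
                            channels = channels, rate = rate, dt = dt,
                            distance_bins = distance_bins, seed = seed),
                       class = "spike_pair_suite"))
    }
  }
  stop_liquidens("could not realize non-decreasing bin distances",
                 "generation_failure")
}

# Render a soft-edged oriented bar glyph: intensity falls off as a Gaussian
# of the perpendicular distance to a segment of half-length `half_len`
# through `center` at angle `angle` (radians); ends are capped smoothly.
render_bar_glyph <- function(size, angle, center, half_len, width) {
  xs <- matrix(rep(seq_len(size), size), size, size)        # column index
  ys <- matrix(rep(seq_len(size), each = size), size, size) # row index
  dx <- xs - center[1]
  dy <- ys - center[2]
  along <- dx * cos(angle) + dy * sin(angle)
  perp <- -dx * sin(angle) + dy * cos(angle)
  over <- pmax(abs(along) - half_len, 0)
  img <- 255 * exp(-(perp / width)^2) * exp(-(over / width)^2)
  pmin(pmax(img, 0), 255)
}

#' Clustered image set: glyph classes with transformed variants
#'
#' Renders `n_classes` parametric glyph classes (soft oriented bars at
#' class-specific orientations, with small per-image pose jitter) and emits
#' four clusters of each image: `original`, `rotated` (orientation offset by
#' `rot_deg` degrees, random sign), `shifted` (center offset by `shift_px`
#' pixels in a random direction), and `noisy` (additive Gaussian pixel noise
#' of standard deviation `noise_sd` intensity units, clipped to `[0, 255]`).
#' With all transform parameters zero the four clusters are identical. The
#' class/cluster structure (mean within-class pixel distance below mean
#' between-class distance) is asserted at generation time.
#'
#' @param n_classes number of glyph classes (>= 2).
#' @param per_cell images per (class, cluster) cell.
#' @param size image side in pixels (default 16).
#' @param rot_deg,shift_px,noise_sd transform magnitudes (defaults 15
#'   degrees, 2 px, 20 intensity units).
#' @param seed integer seed.
#' @return an object of class `clustered_images`: `images` (list of
#'   `size x size` matrices in `[0, 255]`), `labels` (integer in
#'   `1..n_classes`), `clusters` (character tags), and the parameters.
#' @export
gen_clustered_images <- function(n_classes = 5, per_cell = 8, size = 16,
                                 rot_deg = 15, shift_px = 2, noise_sd = 20,
                                 seed = 1) {
  if (!is_count(n_classes, 2L))
    stop_liquidens("need at least 2 classes", "degenerate_size")
  stopifnot(is_count(per_cell, 1L), is_count(size, 4L), noise_sd >= 0)
  if (abs(shift_px) >= size / 2 || abs(rot_deg) >= 90)
    stop_liquidens("transform would push glyphs out of frame",
                   "generation_failure")
  cluster_tags <- c("original", "rotated", "shifted", "noisy")
  half_len <- 0.35 * size
  width <- 0.09 * size
  with_seed(seed, {
    images <- list()
    labels <- integer(0)
    clusters <- character(0)
    for (cls in seq_len(n_classes)) {
      base_angle <- (cls - 1) * pi / n_classes
      for (j in seq_len(per_cell)) {
        angle <- base_angle + rnorm(1, 0, 2 * pi / 180)
        center <- (size + 1) / 2 + rnorm(2, 0, 0.4)
        rot_sign <- sample(c(-1, 1), 1)
        shift_dir <- runif(1, 0, 2 * pi)
        base <- render_bar_glyph(size, angle, center, half_len, width)
        noise <- matrix(rnorm(size * size, 0, 1), size, size)
        variants <- list(
          original = base,
          rotated = render_bar_glyph(size, angle + rot_sign * rot_deg *
                                       pi / 180, center, half_len, width),
          shifted = render_bar_glyph(size, angle, center + shift_px *
                                       c(cos(shift_dir), sin(shift_dir)),
                                     half_len, width),
          noisy = pmin(pmax(base + noise_sd * noise, 0), 255)
        )
        for (tag in cluster_tags) {
          images[[length(images) + 1L]] <- variants[[tag]]
          labels <- c(labels, cls)
          clusters <- c(clusters, tag)
        }
      }
    }
    out <- structure(list(images = images, labels = labels,
                          clusters = clusters, n_classes = n_classes,
                          per_cell = per_cell, size = size,
                          rot_deg = rot_deg, shift_px = shift_px,
                          noise_sd = noise_sd, seed = seed),
                     class = "clustered_images")
    disp <- image_dispersion(out)
    if (disp$within >= disp$between)
      stop_liquidens(
        "generated set lacks class structure (within >= between dispersion)",
        "generation_failure")
    out
  })
}

# Mean within-class vs between-class Euclidean distance in pixel space.
image_dispersion <- function(x) {
  X <- t(vapply(x$images, as.vector, numeric(x$size^2)))
  D <- as.matrix(stats::dist(X))
  same <- outer(x$labels, x$labels, "==") & upper.tri(D)
  diff <- outer(x$labels, x$labels, "!=") & upper.tri(D)
  list(within = mean(D[same]), between = mean(D[diff]))
}

#' @export
print.clustered_images <- function(x, ...) {
  cat(sprintf(
    "<clustered_images> %d images: %d classes x %d per cell x 4 clusters (%dx%d px)\n",
    length(x$images), x$n_classes, x$per_cell, x$size, x$size))
  invisible(x)
}

#' Class-structured channel-intensity signal set
#'
#' A synthetic stand-in for cochleagram output: each class gets a smooth
#' random spectro-temporal template (a sum of low-frequency cosine ridges
#' over the channel-by-time plane) scaled into `[0, p_max]`; each sample is
#' the class template plus Gaussian noise, clipped back to `[0, 1]`. With
#' `noise_sd = 0` all samples of a class are identical.
#'
#' @param n_classes number of classes.
#' @param per_class samples per class (classes are balanced).
#' @param n_channels channels (default 39).
#' @param n_steps time steps.
#' @param dt step, ms.
#' @param p_max template ceiling: maximum per-step firing probability.
#' @param noise_sd additive noise standard deviation (probability units).
#' @param seed integer seed.
#' @return an object of class `channel_signal_set`: `signals` (list of
#'   [channel_stimulus()]), `labels`, and parameters.
#' @export
gen_channel_signals <- function(n_classes = 4, per_class = 10,
                                n_channels = 39, n_steps = 600, dt = 0.5,
                                p_max = 0.1, noise_sd = 0.02, seed = 1) {
  stopifnot(is_count(n_classes, 1L), is_count(per_class, 1L),
            is_count(n_channels, 1L), is_count(n_steps, 1L),
            p_max > 0, p_max <= 1, noise_sd >= 0)
  with_seed(seed, {
    ch <- seq_len(n_channels) / n_channels
    tm <- seq_len(n_steps) / n_steps
    templates <- lapply(seq_len(n_classes), function(cls) {
      z <- matrix(0, n_channels, n_steps)
      for (h in 1:3) {
        a <- runif(1, 0.5, 1)
        fc <- sample(1:3, 1)
        ft <- sample(1:3, 1)
        phase <- runif(1, 0, 2 * pi)
        z <- z + a * outer(ch, tm, function(c, t)
          cos(2 * pi * (fc * c + ft * t) + phase))
      }
      (z - min(z)) / (max(z) - min(z)) * p_max
    })
    signals <- list()
    labels <- integer(0)
    for (cls in seq_len(n_classes)) {
      for (j in seq_len(per_class)) {
        s <- templates[[cls]]
        if (noise_sd > 0)
          s <- s + matrix(rnorm(length(s), 0, noise_sd),
                          n_channels, n_steps)
        signals[[length(signals) + 1L]] <-
          channel_stimulus(pmin(pmax(s, 0), 1), dt = dt)
        labels <- c(labels, cls)
      }
    }
    structure(list(signals = signals, labels = labels,
                   n_channels = n_channels, n_steps = n_steps, dt = dt,
                   p_max = p_max, noise_sd = noise_sd, seed = seed),
              class = "channel_signal_set")
  })
}
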