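#' Exponentially filtered liquid state
#'
#' The continuous-time state used by the kernel-quality measures: each
#' neuron's spike train is passed through a linear filter with exponential
#' decay (time constant 30 ms by default), so entry `j` at query time `t` is
#' \eqn{\sum_{t_s \le t} e^{-(t - t_s)/\tau_{filter}}} over the spikes of
#' neuron `j`.
#'
#' @param spikes a [spike_record()] or an `ensemble_spikes` list (states are
#'   concatenated in ensemble order).
#' @param t query time, ms, within `[0, duration]`.
#' @param tau_filter filter time constant, ms.
#' @return numeric vector with one non-negative entry per neuron.
#' @export
filtered_state <- function(spikes, t, tau_filter = 30) {
  if (inherits(spikes, "ensemble_spikes"))
    return(unlist(lapply(spikes, filtered_state, t = t,
                         tau_filter = tau_filter), use.names = FALSE))
  stopifnot(inherits(spikes, "spike_record"), tau_filter > 0)
  if (t < 0 || t > spikes$duration)
    stop_liquidens("query time outside the record", "range_error")
  x <- numeric(spikes$n_neurons)
  sel <- spikes$time <= t
  if (any(sel)) {
    contrib <- exp(-(t - spikes$time[sel]) / tau_filter)
    agg <- rowsum(contrib, spikes$neuron[sel])
    x[as.integer(rownames(agg))] <- agg[, 1]
  }
  x
}

#' @rdname filtered_state
#' @param times vector of query times.
#' @return `filtered_states()` returns a matrix (neurons x times).
#' @export
filtered_states <- function(spikes, times, tau_filter = 30) {
  vapply(times, function(t) filtered_state(spikes, t, tau_filter),
         numeric(if (inherits(spikes, "ensemble_spikes"))
           sum(vapply(spikes, function(r) r$n_neurons, integer(1)))
           else spikes$n_neurons))
}

#' Pairwise separation between two state trajectories
#'
#' The mean, over common sample times, of the Euclidean norm of the
#' difference between two filtered state trajectories:
#' \eqn{SP_{pw} = \frac{1}{N} \sum_n \lVert x_u(t_n) - x_v(t_n) \rVert}.
#'
#' @param x_u,x_v matrices (neurons x sample times) of filtered states at
#'   common sample times, e.g. from [filtered_states()].
#' @return a non-negative scalar.
#' @export
pairwise_separation <- function(x_u, x_v) {
  x_u <- as.matrix(x_u)
  x_v <- as.matrix(x_v)
  if (!all(dim(x_u) == dim(x_v)) || ncol(x_u) < 1)
    stop_liquidens("state series must have equal non-empty dimensions",
                   "incompatible_states")
  mean(sqrt(colSums((x_u - x_v)^2)))
}

#' Numerical rank of a state matrix
#'
#' Rank computed from the singular value decomposition: singular values above
#' `rel_tol` times the largest count toward the rank. Filtered states from
#' finite spike counts are noisy, so an exact-zero test would always return
#' full rank; the relative tolerance (default 1e-6) is part of the measure.
#'
#' @param M numeric matrix (liquid dimension x number of states).
#' @param rel_tol relative singular-value tolerance.
#' @return an object of class `rank_result`: `list(rank, singular_values,
#'   tolerance)`.
#' @export
numerical_rank <- function(M, rel_tol = 1e-6) {
  M <- as.matrix(M)
  if (length(M) == 0)
    stop_liquidens("empty state matrix", "degenerate_size")
  if (any(!is.finite(M)))
    stop_liquidens("non-finite entries in state matrix", "numerical_state")
  sv <- svd(M, nu = 0, nv = 0)$d
  tol <- rel_tol * max(sv, 0)
  structure(list(rank = if (max(sv) == 0) 0L else sum(sv > tol),
                 singular_values = sv, tolerance = tol),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf("<rank_result> rank %d of %d singular values (tol %.3g)\n",
              x$rank, length(x$singular_values), x$tolerance))
  invisible(x)
}

# Simulate one input through a liquid or ensemble and return the filtered
# state at t0 (all liquid neurons; ensembles concatenate in ensemble order).
state_at <- function(topo, input, t0, dt, params, tau_filter, engine = "cpp") {
  rec <- if (inherits(topo, "ensemble_topology"))
    run_ensemble(topo, input, T = input$duration, dt = dt, params = params,
                 engine = engine)
  else run_liquid(topo, input, T = input$duration, dt = dt, params = params,
                  engine = engine)
  filtered_state(rec, t0, tau_filter)
}

#' Rank-based separation of a liquid over a set of stimuli
#'
#' Runs each of `m` distinct input spike trains through the same (fixed)
#' topology, collects the filtered states at `t0` as the columns of a state
#' matrix, and returns its [numerical_rank()]. Higher rank indicates better
#' linear separation of the inputs by the liquid.
#'
#' @param topo a `liquid_topology` or `ensemble_topology`.
#' @param inputs list of `m >= 2` [spike_record()]s over the topology's
#'   input lines.
#' @param t0 sample time, ms; defaults to the stimulus end.
#' @param dt simulation step, ms.
#' @param params a [neuron_params()].
#' @param tau_filter state filter constant, ms.
#' @param rel_tol rank tolerance, see [numerical_rank()].
#' @return a `rank_result`.
#' @export
separation_rank <- function(topo, inputs, t0 = NULL, dt = 0.5,
                            params = neuron_params(), tau_filter = 30,
                            rel_tol = 1e-6) {
  stopifnot(is.list(inputs), length(inputs) >= 2)
  if (is.null(t0)) t0 <- inputs[[1]]$duration
  cols <- lapply(inputs, state_at, topo = topo, t0 = t0, dt = dt,
                 params = params, tau_filter = tau_filter)
  numerical_rank(do.call(cbind, cols), rel_tol = rel_tol)
}

#' Rank-based generalization over jittered stimuli
#'
#' As [separation_rank()], but the `m` columns come from jittered replicas of
#' a small set of base inputs (cycled in order), produced by [jitter_train()].
#' A *lower* rank indicates better generalization: the liquid maps same-class
#' perturbed inputs to (nearly) linearly dependent states.
#'
#' @inheritParams separation_rank
#' @param base_inputs list of base [spike_record()]s.
#' @param sigma jitter standard deviation, ms.
#' @param m number of jittered columns (>= 2).
#' @param seed integer seed for the jitter draws.
#' @return a `rank_result`.
#' @export
generalization_rank <- function(topo, base_inputs, sigma = 4, m = 20,
                                t0 = NULL, dt = 0.5,
                                params = neuron_params(), tau_filter = 30,
                                rel_tol = 1e-6, seed = NULL) {
  stopifnot(is.list(base_inputs), length(base_inputs) >= 1, m >= 2)
  if (is.null(t0)) t0 <- base_inputs[[1]]$duration
  jittered <- lapply(seq_len(m), function(k) {
    base <- base_inputs[[((k - 1) %% length(base_inputs)) + 1]]
    jitter_train(base, sigma,
                 seed = if (is.null(seed)) NULL else derive_seed(seed, k))
  })
  cols <- lapply(jittered, state_at, topo = topo, t0 = t0, dt = dt,
                 params = params, tau_filter = tau_filter)
  numerical_rank(do.call(cbind, cols), rel_tol = rel_tol)
}

#' Within- and between-class scatter of labeled states
#'
#' Computes empirical class priors, class means, the global mean, the
#' within-class scatter \eqn{S_w = \sum_i P(\omega_i) \hat\Sigma_i}
#' (prior-weighted sample covariances, `n - 1` denominator) and the
#' between-class scatter
#' \eqn{S_b = \sum_i P(\omega_i) (\mu_i - \mu_g)(\mu_i - \mu_g)^T}.
#'
#' @param states numeric matrix, one row per sample.
#' @param labels class label per row; every class needs at least 2 samples.
#' @return an object of class `scatter_stats`: `class_means`, `global_mean`,
#'   `priors`, `S_w`, `S_b`, `tr_sw`, `tr_sb`, `labels_levels`.
#' @examples
#' s <- scatter_matrices(matrix(c(0, 2, 4, 6)), c("a", "a", "b", "b"))
#' s$tr_sb / s$tr_sw  # discriminant ratio = 2
#' @export
scatter_matrices <- function(states, labels) {
  states <- as.matrix(states)
  if (nrow(states) < 2)
    stop_liquidens("need at least 2 samples", "insufficient_class_data")
  stopifnot(length(labels) == nrow(states))
  f <- factor(labels)
  counts <- table(f)
  if (any(counts < 2))
    stop_liquidens("every class needs >= 2 samples for a defined covariance",
                   "insufficient_class_data")
  d <- ncol(states)
  lv <- levels(f)
  priors <- as.numeric(counts) / nrow(states)
  cm <- vapply(lv, function(cl)
    colMeans(states[f == cl, , drop = FALSE]), numeric(d))
  class_means <- if (d == 1) matrix(cm, ncol = 1) else t(cm)
  global_mean <- colMeans(states)
  S_w <- matrix(0, d, d)
  S_b <- matrix(0, d, d)
  for (k in seq_along(lv)) {
    Xk <- states[f == lv[k], , drop = FALSE]
    S_w <- S_w + priors[k] * cov(Xk)
    dk <- class_means[k, ] - global_mean
    S_b <- S_b + priors[k] * tcrossprod(dk)
  }
  structure(list(class_means = class_means, global_mean = global_mean,
                 priors = priors, S_w = S_w, S_b = S_b,
                 tr_sw = sum(diag(S_w)), tr_sb = sum(diag(S_b)),
                 labels_levels = lv),
            class = "scatter_stats")
}

#' Discriminant ratio of labeled liquid states
#'
#' `DR = tr(S_b) / tr(S_w)`: a scale- and translation-invariant scalar that
#' rises with between-class dispersion (separation) and falls with
#' within-class dispersion (loss of approximation). It stays defined when the
#' scatter matrices are singular (states of dimension much larger than the
#' sample count), which is exactly the regime where the classical Fisher
#' ratio [fisher_ratio()] breaks down.
#'
#' @param stats a `scatter_stats` object from [scatter_matrices()].
#' @return a non-negative scalar.
#' @export
discriminant_ratio <- function(stats) {
  stopifnot(inherits(stats, "scatter_stats"))
  if (stats$tr_sw <= 0)
    stop_liquidens("tr(S_w) is zero: degenerate within-class dispersion",
                   "degenerate_dispersion")
  stats$tr_sb / stats$tr_sw
}

#' Fisher discriminant ratio
#'
#' `FDR = tr(S_w^{-1} S_b)`, the classical LDA objective. Errors (rather than
#' silently regularizing) when `S_w` is ill-conditioned at the declared
#' threshold — the high-dimension/low-sample regime in which the trace-ratio
#' [discriminant_ratio()] is the usable surrogate.
#'
#' @param stats a `scatter_stats` object.
#' @param rcond_min minimum acceptable reciprocal condition number of `S_w`.
#' @return a scalar.
#' @export
fisher_ratio <- function(stats, rcond_min = 1e-10) {
  stopifnot(inherits(stats, "scatter_stats"))
  rc <- rcond(stats$S_w)
  if (!is.finite(rc) || rc < rcond_min)
    stop_liquidens(sprintf(
      "S_w is singular or ill-conditioned (rcond %.3g)", rc),
      "singular_scatter")
  sum(diag(solve(stats$S_w, stats$S_b)))
}
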