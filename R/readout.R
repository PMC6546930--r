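#' Liquid state vector: normalized excitatory spike counts
#'
#' Counts the spikes of each excitatory neuron (indices `1..n_e`) over
#' `[0, T]` and divides all counts by the maximum count in the sample, so
#' entries lie in `[0, 1]` regardless of firing rates (a zero vector if the
#' record is empty). This per-sample max normalization is the default reading
#' of a "normalized spike count"; dividing by the rate ceiling
#' `T * r_max / 1000` instead is available via `normalize = "rate"`.
#'
#' @param spikes a [spike_record()] from a liquid.
#' @param n_e number of excitatory neurons (the leading indices).
#' @param T counting window, ms; defaults to the record duration.
#' @param normalize `"max"` (default) or `"rate"`.
#' @param r_max rate ceiling in Hz used when `normalize = "rate"`.
#' @return numeric vector of length `n_e` with entries in `[0, 1]`.
#' @export
extract_state <- function(spikes, n_e, T = spikes$duration,
                          normalize = c("max", "rate"), r_max = 63.75) {
  normalize <- match.arg(normalize)
  stopifnot(inherits(spikes, "spike_record"), is_count(n_e, 1L),
            T <= spikes$duration)
  sel <- spikes$time <= T & spikes$neuron <= n_e
  counts <- tabulate(spikes$neuron[sel], nbins = n_e)
  if (normalize == "max") {
    m <- max(counts)
    if (m == 0) numeric(n_e) else counts / m
  } else {
    pmin(counts / (T * r_max / 1000), 1)
  }
}

#' Concatenate per-liquid state vectors
#'
#' Joins the state vectors of an ensemble's liquids in ensemble order. The
#' total length equals the sum of excitatory counts, which matches the
#' single-liquid excitatory dimension at the same neuron budget — so readout
#' parameter counts are identical for the baseline and the ensemble.
#'
#' @param per_liquid list of numeric state vectors, ordered by ensemble index.
#' @return one concatenated numeric vector.
#' @export
concatenate_states <- function(per_liquid) {
  stopifnot(is.list(per_liquid), length(per_liquid) >= 1)
  unlist(per_liquid, use.names = FALSE)
}

#' @rdname concatenate_states
#' @param records an `ensemble_spikes` list from [run_ensemble()].
#' @param ensemble the matching `ensemble_topology`.
#' @param T counting window, ms.
#' @param ... passed to [extract_state()].
#' @export
ensemble_state <- function(records, ensemble, T = records[[1]]$duration,
                           ...) {
  stopifnot(inherits(records, "ensemble_spikes"),
            inherits(ensemble, "ensemble_topology"))
  concatenate_states(lapply(seq_along(records), function(k) {
    extract_state(records[[k]], n_e = ensemble$liquids[[k]]$n_e, T = T, ...)
  }))
}

#' Training configuration for the linear readout
#'
#' @param learning_rate SGD step size.
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param seed integer seed (weight init and epoch shuffles).
#' @param init_sd standard deviation of the Gaussian weight initialization.
#' @return a list of class `readout_config`.
#' @export
readout_config <- function(learning_rate = 0.5, epochs = 100,
                           batch_size = 32, seed = 1, init_sd = 0.01) {
  stopifnot(learning_rate > 0, is_count(epochs, 1L), is_count(batch_size, 1L))
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 init_sd = init_sd),
            class = "readout_config")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Turn integer labels (1..L) into one-hot target rows.
one_hot <- function(labels, L) {
  Y <- matrix(0, length(labels), L)
  Y[cbind(seq_along(labels), as.integer(labels))] <- 1
  Y
}

#' Train a linear softmax readout
#'
#' Fits a single linear layer with softmax output by mini-batch stochastic
#' gradient descent on the cross-entropy loss. Targets may be integer class
#' labels in `1..L` (converted to one-hot rows) or an arbitrary
#' target-distribution matrix — e.g. the uniform "inhibitory label" rows used
#' by clustered training-space division. Deterministic per
#' `config$seed`.
#'
#' @param states numeric matrix, one state vector per row.
#' @param targets integer labels in `1..L`, or an `n x L` matrix of target
#'   rows (each summing to 1).
#' @param L number of classes; required when `targets` is a label vector
#'   whose maximum may undershoot `L`. Inferred otherwise.
#' @param config a [readout_config()].
#' @return an object of class `readout_model`: weight matrix `W` (`L x d`),
#'   bias `b`, the per-epoch mean loss trace, `L`, and the config.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, -2), 20), matrix(rnorm(40, 2), 20))
#' m <- train_readout(x, rep(1:2, each = 20), config = readout_config())
#' mean(predict(m, x)$class == rep(1:2, each = 20))
#' @export
train_readout <- function(states, targets, L = NULL,
                          config = readout_config()) {
  states <- as.matrix(states)
  n <- nrow(states)
  d <- ncol(states)
  if (n == 0)
    stop_liquidens("no training data", "insufficient_data")
  if (is.matrix(targets)) {
    Y <- targets
    if (is.null(L)) L <- ncol(Y)
    stopifnot(ncol(Y) == L, nrow(Y) == n)
  } else {
    if (is.null(L)) L <- max(as.integer(targets))
    stopifnot(length(targets) == n, all(targets >= 1), all(targets <= L))
    Y <- one_hot(targets, L)
  }
  if (n < L)
    stop_liquidens("need at least one sample per class", "insufficient_data")
  withr::with_seed(config$seed, {
    W <- matrix(rnorm(L * d, 0, config$init_sd), L, d)
    b <- numeric(L)
    loss_trace <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, n)]
        X <- states[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        P <- softmax_rows(X %*% t(W) + matrix(b, length(idx), L, byrow = TRUE))
        losses <- c(losses, -mean(rowSums(Yb * log(pmax(P, 1e-12)))))
        G <- (P - Yb) / length(idx)           # d(loss)/d(logits)
        W <- W - config$learning_rate * t(G) %*% X
        b <- b - config$learning_rate * colSums(G)
      }
      loss_trace[ep] <- mean(losses)
    }
    structure(list(W = W, b = b, L = L, d = d, loss_trace = loss_trace,
                   config = config),
              class = "readout_model")
  })
}

#' Readout scores and class decision
#'
#' Scores are `softmax(W s + b)`; the class is the argmax with lowest-index
#' tie-break (class indices are 1-based).
#'
#' @param object a `readout_model`.
#' @param states a state vector or a matrix with one state per row.
#' @param ... unused.
#' @return `list(scores, class)`: scores is an `n x L` matrix of class
#'   probabilities (rows sum to 1), class an integer vector.
#' @export
predict.readout_model <- function(object, states, ...) {
  if (is.null(dim(states))) states <- matrix(states, nrow = 1)
  if (ncol(states) != object$d)
    stop_liquidens(sprintf("state dimension %d does not match model (%d)",
                           ncol(states), object$d), "incompatible_state")
  scores <- softmax_rows(states %*% t(object$W) +
                           matrix(object$b, nrow(states), object$L,
                                  byrow = TRUE))
  list(scores = scores, class = apply(scores, 1, which.max))
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf("<readout_model> %d classes x %d features, final loss %.4f\n",
              x$L, x$d, x$loss_trace[length(x$loss_trace)]))
  invisible(x)
}

#' Random division of a training set across readouts
#'
#' A seeded permutation of `1..n` split into `n_ens` disjoint subsets of size
#' `floor(n / n_ens)`, with the remainder going to the earliest subsets.
#' Subsets cover the full index set.
#'
#' @param n number of training samples (>= `n_ens`).
#' @param n_ens number of subsets.
#' @param seed integer seed.
#' @return list of `n_ens` integer index vectors.
#' @export
random_division <- function(n, n_ens, seed) {
  stopifnot(is_count(n, 1L), is_count(n_ens, 1L), n >= n_ens)
  base <- n %/% n_ens
  sizes <- rep(base, n_ens) + as.integer(seq_len(n_ens) <= n %% n_ens)
  with_seed(seed, {
    perm <- sample.int(n)
    split(perm, rep(seq_len(n_ens), sizes))
  })
}

#' Inhibitory label vector and foreign-instance bookkeeping
#'
#' `inhibitory_label(L)` is the uniform target row with every entry `1/L`,
#' used as the training target of foreign-cluster instances so a local
#' readout emits low scores on clusters it was not trained for.
#' `foreign_instance_fraction(n_ens, x_f)` is the resulting percentage of
#' foreign instances in each local training set,
#' `100 (N_{ens}-1) x_f / ((N_{ens}-1) x_f + 100)`; at the defaults
#' (`n_ens = 4`, `x_f = 10`) it is 23%. `per_set_share(L, n_ens)` is the
#' share of the training space attached to each of the `L + n_ens - 1`
#' constituent "sets" when the sets are balanced: `100 / (L + n_ens - 1)`
#' percent (7.7% for ten classes and four clusters).
#'
#' @param L number of classes.
#' @return `inhibitory_label()`: numeric vector summing to 1.
#' @export
inhibitory_label <- function(L) {
  stopifnot(is_count(L, 1L))
  rep(1 / L, L)
}

#' @rdname inhibitory_label
#' @param n_ens number of clusters / local readouts.
#' @param x_f foreign sampling percentage in `[0, 100]`.
#' @export
foreign_instance_fraction <- function(n_ens, x_f = 10) {
  stopifnot(is_count(n_ens, 1L), x_f >= 0, x_f <= 100)
  100 * (n_ens - 1) * x_f / ((n_ens - 1) * x_f + 100)
}

#' @rdname inhibitory_label
#' @export
per_set_share <- function(L, n_ens) {
  stopifnot(is_count(L, 1L), is_count(n_ens, 1L))
  100 / (L + n_ens - 1)
}

#' Clustered division of a training set with the inhibition criterion
#'
#' Builds one training set per cluster: all of the cluster's own samples with
#' one-hot targets, plus `x_f` percent of every other cluster ("foreign
#' instances"), sampled without replacement and stratified per source
#' cluster, with targets replaced by the inhibitory label vector (every entry
#' `1/L`).
#'
#' @param labels integer class labels in `1..L` for every training sample.
#' @param clusters cluster tag per sample (factor or character).
#' @param L number of classes.
#' @param x_f foreign sampling percentage (default 10).
#' @param seed integer seed.
#' @return named list (one entry per cluster level) of
#'   `list(indices, targets, foreign)`: global sample indices, the `|set| x L`
#'   target matrix, and a logical marking foreign rows.
#' @export
clustered_division <- function(labels, clusters, L, x_f = 10, seed = 1) {
  stopifnot(length(labels) == length(clusters), x_f >= 0, x_f <= 100)
  f <- factor(clusters)
  if (nlevels(f) < 2)
    stop_liquidens("need at least 2 clusters", "insufficient_class_data")
  idx_by_cluster <- split(seq_along(labels), f)
  if (any(vapply(idx_by_cluster, length, integer(1)) == 0))
    stop_liquidens("empty cluster", "insufficient_class_data")
  with_seed(seed, {
    out <- lapply(levels(f), function(cl) {
      own <- idx_by_cluster[[cl]]
      foreign <- integer(0)
      for (other in setdiff(levels(f), cl)) {
        pool <- idx_by_cluster[[other]]
        k <- round(length(pool) * x_f / 100)
        if (k > 0) foreign <- c(foreign, sample(pool, k))
      }
      targets <- rbind(one_hot(labels[own], L),
                       matrix(rep(inhibitory_label(L), length(foreign)),
                              ncol = L, byrow = TRUE))
      list(indices = c(own, foreign), targets = targets,
           foreign = c(rep(FALSE, length(own)), rep(TRUE, length(foreign))))
    })
    names(out) <- levels(f)
    out
  })
}

#' Fuse per-liquid readout scores into one class decision
#'
#' The default fusion is the maximum over all local scores: the argmax over
#' the concatenation of the local score vectors (in liquid order), mapped
#' back to a class index, with lowest-(liquid, class) tie-break. Majority
#' vote over the local argmax decisions is available as an alternative
#' (ties again broken toward the lowest class index).
#'
#' @param local_scores list of length-`L` score vectors, one per local
#'   readout.
#' @param rule `"max"` (default) or `"majority"`.
#' @return an integer class index in `1..L`.
#' @export
mlmr_classify <- function(local_scores, rule = c("max", "majority")) {
  rule <- match.arg(rule)
  stopifnot(is.list(local_scores), length(local_scores) >= 1)
  L <- length(local_scores[[1]])
  stopifnot(all(vapply(local_scores, length, integer(1)) == L))
  if (rule == "max") {
    flat <- unlist(local_scores, use.names = FALSE)
    ((which.max(flat) - 1L) %% L) + 1L
  } else {
    votes <- vapply(local_scores, which.max, integer(1))
    tab <- tabulate(votes, nbins = L)
    which.max(tab)
  }
}
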