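#' Pathway connectivity specification
#'
#' Percentage connectivity per pathway of the liquid. The defaults for the
#' recurrent pathways (E to E 40, E to I 40, I to E 50, I to I 0) are the
#' values used across all tasks in the reference configuration; the input
#' pathway differs per task, so `p_in_e` has no default. Input lines never
#' project to inhibitory neurons (`p_in_i` is fixed at 0).
#'
#' @param p_in_e input-to-excitatory percentage, in `[0, 100]`.
#' @param p_e_e,p_e_i,p_i_e,p_i_i recurrent pathway percentages.
#' @return an object of class `connectivity_spec`.
#' @seealso [connectivity_preset()] for the task presets.
#' @export
connectivity_spec <- function(p_in_e, p_e_e = 40, p_e_i = 40,
                              p_i_e = 50, p_i_i = 0) {
  s <- list(p_in_e = p_in_e, p_e_e = p_e_e, p_e_i = p_e_i,
            p_i_e = p_i_e, p_i_i = p_i_i, p_in_i = 0)
  for (nm in names(s)) {
    v <- s[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 100)
      stop_liquidens(sprintf("connectivity_spec: '%s' must be in [0, 100]", nm),
                     "invalid_params")
  }
  structure(s, class = "connectivity_spec")
}

#' @rdname connectivity_spec
#' @param task one of `"mnist"`, `"e-mnist"` (both `p_in_e` = 10),
#'   `"ti10"` (`p_in_e` = 23), `"ti-alpha"` (`p_in_e` = 34).
#' @export
connectivity_preset <- function(task = c("mnist", "e-mnist", "ti10",
                                         "ti-alpha")) {
  task <- match.arg(task)
  p_in <- switch(task, "mnist" = 10, "e-mnist" = 10, "ti10" = 23,
                 "ti-alpha" = 34)
  connectivity_spec(p_in_e = p_in)
}

#' Split a neuron budget into excitatory and inhibitory counts
#'
#' The liquid keeps excitatory and inhibitory neurons at a 4:1 ratio, as in
#' the auditory cortex: `n_i = round(n_total / 5)`, `n_e = n_total - n_i`.
#'
#' @param n_total total neuron count (>= 2).
#' @return `list(n_e, n_i)`.
#' @examples
#' split_ei(500)  # 400 excitatory, 100 inhibitory
#' @export
split_ei <- function(n_total) {
  if (!is_count(n_total) || n_total < 2)
    stop_liquidens("n_total must be an integer >= 2", "degenerate_size")
  n_i <- as.integer(round(n_total / 5))
  list(n_e = as.integer(n_total) - n_i, n_i = n_i)
}

#' Sample a random binary connection mask
#'
#' Each admissible entry is 1 independently with probability `p / 100`
#' (Bernoulli sampling, so the realized percentage fluctuates binomially
#' around `p`). The convention is rows = post neurons, columns = pre neurons.
#'
#' @param n_post,n_pre matrix dimensions.
#' @param p percentage connectivity in `[0, 100]`.
#' @param seed optional seed; if `NULL`, draws from the ambient RNG stream.
#' @param exclude_self zero the diagonal (square matrices only), preventing
#'   self-connections.
#' @return a 0/1 matrix of dimension `n_post x n_pre`.
#' @export
sample_mask <- function(n_post, n_pre, p, seed = NULL, exclude_self = FALSE) {
  stopifnot(is_count(n_post), is_count(n_pre), p >= 0, p <= 100)
  m <- with_seed(seed, {
    matrix(as.numeric(runif(n_post * n_pre) < p / 100), n_post, n_pre)
  })
  if (exclude_self && n_post == n_pre && n_post > 0) diag(m) <- 0
  m
}

#' Realized percentage connectivity of a mask
#'
#' `100 * sum(mask) / (rows * cols)`, the empirical counterpart of the
#' nominal pathway percentage.
#'
#' @param mask a binary matrix.
#' @return percentage in `[0, 100]`.
#' @export
realized_connectivity <- function(mask) {
  if (!is.matrix(mask) || length(mask) == 0)
    stop_liquidens("mask must be a non-empty matrix", "degenerate_size")
  100 * sum(mask != 0) / length(mask)
}

#' Build a random liquid topology
#'
#' Splits the budget 4:1 into excitatory/inhibitory populations
#' ([split_ei()]), samples one Bernoulli mask per pathway at the requested
#' percentages (input-to-inhibitory is always empty), and draws uniform(0, 1)
#' strengths on the mask support. Self-connections are excluded in the square
#' pathways (E to E, I to I). Inhibitory weights are stored as positive
#' magnitudes; inhibition acts through the inhibitory reversal potential.
#' Deterministic per seed.
#'
#' @param n_total total neuron budget (>= 2).
#' @param spec a [connectivity_spec()].
#' @param n_inputs number of input lines (>= 1).
#' @param seed integer seed.
#' @return an object of class `liquid_topology` with fields `n_e`, `n_i`,
#'   `n_inputs`, `masks` and `weights` (lists with entries `in_e`, `e_e`,
#'   `e_i`, `i_e`, `i_i`, all post x pre), and `seed`.
#' @examples
#' topo <- build_liquid(100, connectivity_preset("mnist"), n_inputs = 64,
#'                      seed = 7)
#' realized_connectivity(topo$masks$e_e)
#' @export
build_liquid <- function(n_total, spec, n_inputs, seed) {
  stopifnot(inherits(spec, "connectivity_spec"))
  if (!is_count(n_inputs, min = 1L))
    stop_liquidens("n_inputs must be an integer >= 1", "degenerate_size")
  ei <- split_ei(n_total)
  n_e <- ei$n_e
  n_i <- ei$n_i
  built <- with_seed(seed, {
    masks <- list(
      in_e = sample_mask(n_e, n_inputs, spec$p_in_e),
      e_e  = sample_mask(n_e, n_e, spec$p_e_e, exclude_self = TRUE),
      e_i  = sample_mask(n_i, n_e, spec$p_e_i),
      i_e  = sample_mask(n_e, n_i, spec$p_i_e),
      i_i  = sample_mask(n_i, n_i, spec$p_i_i, exclude_self = TRUE)
    )
    weights <- lapply(masks, function(m) {
      w <- matrix(runif(length(m)), nrow(m), ncol(m))
      w * m
    })
    list(masks = masks, weights = weights)
  })
  structure(list(n_e = n_e, n_i = n_i, n_inputs = as.integer(n_inputs),
                 masks = built$masks, weights = built$weights,
                 spec = spec, seed = as.integer(seed)),
            class = "liquid_topology")
}

#' @export
print.liquid_topology <- function(x, ...) {
  cat(sprintf("<liquid_topology> %d E + %d I neurons, %d input lines\n",
              x$n_e, x$n_i, x$n_inputs))
  invisible(x)
}

#' Build an ensemble of independent liquids under a fixed neuron budget
#'
#' Divides `n_total` neurons into `n_ens` mutually unconnected liquids
#' (sizes `floor(n_total / n_ens)`, remainder distributed one-per-liquid from
#' the first) and builds each with [build_liquid()] under a derived sub-seed
#' ([derive_seed()]; liquid `k` uses counter `k - 1`, so `n_ens = 1`
#' reproduces `build_liquid(n_total, ..., seed)` exactly). Every liquid
#' receives the full input line set at `p_in_e`, with its input mask sampled
#' independently.
#'
#' @inheritParams build_liquid
#' @param n_ens number of liquids (>= 1); requires `n_total >= 2 * n_ens`.
#' @return an object of class `ensemble_topology` with fields `liquids`
#'   (list of `liquid_topology`), `n_total`, `n_ens`, and `index_map`
#'   (data frame mapping each liquid's excitatory neurons to global
#'   excitatory indices in concatenation order).
#' @examples
#' ens <- build_ensemble(1000, 4, connectivity_preset("mnist"),
#'                       n_inputs = 64, seed = 1)
#' vapply(ens$liquids, function(l) l$n_e + l$n_i, numeric(1))
#' @export
build_ensemble <- function(n_total, n_ens, spec, n_inputs, seed) {
  if (!is_count(n_ens, min = 1L))
    stop_liquidens("n_ens must be an integer >= 1", "degenerate_size")
  if (!is_count(n_total) || n_total < 2 * n_ens)
    stop_liquidens("n_total must be at least 2 * n_ens", "degenerate_size")
  base <- n_total %/% n_ens
  rem <- n_total %% n_ens
  sizes <- rep(base, n_ens) + as.integer(seq_len(n_ens) <= rem)
  liquids <- lapply(seq_len(n_ens), function(k) {
    build_liquid(sizes[k], spec, n_inputs, derive_seed(seed, k - 1))
  })
  n_e_each <- vapply(liquids, function(l) l$n_e, integer(1))
  index_map <- data.frame(
    liquid = rep(seq_len(n_ens), n_e_each),
    local = unlist(lapply(n_e_each, seq_len)),
    global = seq_len(sum(n_e_each))
  )
  structure(list(liquids = liquids, n_total = as.integer(n_total),
                 n_ens = as.integer(n_ens), index_map = index_map,
                 spec = spec, n_inputs = as.integer(n_inputs),
                 seed = as.integer(seed)),
            class = "ensemble_topology")
}

#' @export
print.ensemble_topology <- function(x, ...) {
  cat(sprintf("<ensemble_topology> %d liquids, %d neurons total, %d inputs\n",
              x$n_ens, x$n_total, x$n_inputs))
  invisible(x)
}

#' Count realized connections per pathway
#'
#' Exact ones-counts of every mask of a liquid or ensemble: per-pathway
#' counts, the liquid-internal subtotal (all recurrent pathways), the input
#' subtotal, and the grand total. For ensembles the counts are summed over
#' member liquids (there are no cross-liquid connections by construction).
#'
#' @param x a `liquid_topology` or `ensemble_topology`.
#' @return named list with entries `in_e`, `e_e`, `e_i`, `i_e`, `i_i`,
#'   `internal`, `input`, `total`.
#' @export
count_connections <- function(x) {
  UseMethod("count_connections")
}

#' @export
count_connections.liquid_topology <- function(x) {
  cnt <- lapply(x$masks, function(m) sum(m != 0))
  internal <- cnt$e_e + cnt$e_i + cnt$i_e + cnt$i_i
  c(cnt, list(internal = internal, input = cnt$in_e,
              total = internal + cnt$in_e))
}

#' @export
count_connections.ensemble_topology <- function(x) {
  per <- lapply(x$liquids, count_connections)
  out <- lapply(names(per[[1]]), function(nm) {
    sum(vapply(per, function(p) p[[nm]], numeric(1)))
  })
  names(out) <- names(per[[1]])
  out
}
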