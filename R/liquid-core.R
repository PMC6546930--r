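#' Per-step operations of the clock-driven simulator
#'
#' These four operations define one simulation step and are exposed both for
#' testing against closed forms and for building custom loops. [run_liquid()]
#' composes them in the fixed order: deliver spikes from the previous step,
#' decay conductances, integrate membranes, threshold and reset.
#'
#' `integrate_membrane()` advances the membrane equation
#' \eqn{\tau \dot V = (E_{rest}-V) + g_e(E_{exc}-V) + g_i(E_{inh}-V)}
#' by one step of length `dt` using the exact exponential update with the
#' conductances frozen within the step:
#' \eqn{V \leftarrow V_\infty + (V - V_\infty) e^{-dt\,(1+g_e+g_i)/\tau}} with
#' \eqn{V_\infty = (E_{rest} + g_e E_{exc} + g_i E_{inh})/(1+g_e+g_i)}.
#' Refractory neurons (those with `t_now <= refractory_until`) hold their
#' reset potential. Conductances are not modified here.
#'
#' @param state a [neuron_state()].
#' @param pop per-neuron parameters from [population_params()].
#' @param dt step length, ms (> 0).
#' @param t_now time at the end of the current step, ms.
#' @return `integrate_membrane()` and `decay_conductances()` return the
#'   updated state; `threshold_and_reset()` returns
#'   `list(state, fired)` with `fired` the sorted global indices of neurons
#'   that spiked; `deliver_spikes()` returns the updated state.
#' @examples
#' pop <- population_params(neuron_params(), n_e = 4, n_i = 1)
#' st <- neuron_state(pop)
#' st$v[1] <- -55
#' st <- integrate_membrane(st, pop, dt = 0.5, t_now = 0.5)
#' @export
integrate_membrane <- function(state, pop, dt, t_now) {
  stopifnot(inherits(state, "neuron_state"), dt > 0)
  if (any(!is.finite(state$v)) || any(!is.finite(state$g_e)) ||
      any(!is.finite(state$g_i)))
    stop_liquidens("non-finite neuron state", "numerical_state")
  denom <- (1 + state$g_e) + state$g_i
  vinf <- ((pop$e_rest + state$g_e * pop$e_exc) + state$g_i * pop$e_inh) / denom
  vnew <- vinf + (state$v - vinf) * exp(-(dt * denom) / pop$tau_mem)
  active <- t_now > state$refractory_until
  state$v[active] <- vnew[active]
  state
}

#' @rdname integrate_membrane
#' @export
threshold_and_reset <- function(state, pop, t_now) {
  stopifnot(inherits(state, "neuron_state"))
  fired <- which(state$v >= pop$thresh & t_now > state$refractory_until)
  if (length(fired)) {
    state$v[fired] <- pop$v_reset[fired]
    state$refractory_until[fired] <- t_now + pop$t_refrac[fired]
  }
  list(state = state, fired = fired)
}

#' @rdname integrate_membrane
#' @export
decay_conductances <- function(state, pop, dt) {
  stopifnot(inherits(state, "neuron_state"), dt > 0)
  state$g_e <- state$g_e * exp(-dt / pop$tau_ge)
  state$g_i <- state$g_i * exp(-dt / pop$tau_gi)
  state
}

#' @rdname integrate_membrane
#' @param weights_e matrix (posts x excitatory pres) of conductance jumps
#'   applied to `g_e`.
#' @param weights_i matrix (posts x inhibitory pres) of jumps applied to
#'   `g_i` (positive magnitudes; inhibition acts through the reversal
#'   potential).
#' @param fired_e,fired_i indices of fired pre neurons within their
#'   populations. Increments are additive across simultaneous spikes.
#' @export
deliver_spikes <- function(state, weights_e, weights_i, fired_e, fired_i) {
  stopifnot(inherits(state, "neuron_state"))
  n <- length(state$g_e)
  if ((length(fired_e) && (nrow(weights_e) != n)) ||
      (length(fired_i) && (nrow(weights_i) != n)))
    stop_liquidens("weight matrix rows do not match population size",
                   "topology_mismatch")
  if (length(fired_e) &&
      (min(fired_e) < 1L || max(fired_e) > ncol(weights_e)))
    stop_liquidens("fired excitatory index out of range", "topology_mismatch")
  if (length(fired_i) &&
      (min(fired_i) < 1L || max(fired_i) > ncol(weights_i)))
    stop_liquidens("fired inhibitory index out of range", "topology_mismatch")
  for (j in sort(as.integer(fired_e))) state$g_e <- state$g_e + weights_e[, j]
  for (j in sort(as.integer(fired_i))) state$g_i <- state$g_i + weights_i[, j]
  state
}

# Stack per-pathway weights into the (n x pre) matrices the engines use.
stacked_weights <- function(topology) {
  w <- topology$weights
  list(
    w_in  = rbind(w$in_e,
                  matrix(0, topology$n_i, topology$n_inputs)),
    w_exc = rbind(w$e_e, w$e_i),
    w_inh = rbind(w$i_e, w$i_i)
  )
}

# Bin input spike times to delivery steps: a spike during step k (time in
# ((k-1) dt, k dt], time 0 counts as "before the run") is delivered at the
# start of step k + 1.
input_delivery_steps <- function(times, dt, n_steps) {
  step <- as.integer(ceiling(times / dt - 1e-9)) + 1L
  step[times <= 0] <- 1L
  step
}

#' Simulate a liquid
#'
#' Runs the clock-driven simulation of one liquid over `[0, T]` at step `dt`.
#' Per step the order is: deliver input and recurrent spikes from the previous
#' step, decay conductances, integrate membranes (exact exponential update
#' with conductances frozen within the step), then threshold and reset. A
#' neuron emits at most one spike per step, and a spike fired during step `k`
#' is stamped with the step-end time `k * dt`. Input spikes are delivered
#' through the same conductance-jump mechanism as recurrent spikes, using the
#' input weight matrix. The run is fully deterministic given the topology and
#' the input.
#'
#' Two engines are provided: `"cpp"` (compiled, the default) and `"r"` (a pure
#' R loop composing [integrate_membrane()] and friends). They execute the same
#' arithmetic in the same order and produce identical spike records; the R
#' engine exists as an audited reference and for instrumentation.
#'
#' @param topology a [build_liquid()] topology.
#' @param input_spikes a [spike_record()] over the topology's input lines.
#' @param T total simulated time, ms; must be a multiple of `dt`. Defaults to
#'   the input record's duration.
#' @param dt step, ms (default 0.5).
#' @param params a [neuron_params()] object.
#' @param engine `"cpp"` or `"r"`.
#' @return a [spike_record()] of the liquid's `n_e + n_i` neurons
#'   (excitatory first).
#' @examples
#' topo <- build_liquid(20, connectivity_spec(p_in_e = 50), n_inputs = 5,
#'                      seed = 1)
#' inp <- encode_channels(channel_stimulus(matrix(0.3, 5, 100)), seed = 2)
#' out <- run_liquid(topo, inp)
#' @export
run_liquid <- function(topology, input_spikes, T = input_spikes$duration,
                       dt = 0.5, params = neuron_params(),
                       engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(topology, "liquid_topology"),
            inherits(input_spikes, "spike_record"),
            T > 0, dt > 0)
  if (abs(T / dt - round(T / dt)) > 1e-9)
    stop_liquidens("T must be a multiple of dt", "invalid_params")
  if (input_spikes$n_neurons != topology$n_inputs)
    stop_liquidens(sprintf(
      "input record has %d lines but topology expects %d",
      input_spikes$n_neurons, topology$n_inputs), "topology_mismatch")
  n_steps <- as.integer(round(T / dt))
  pop <- population_params(params, topology$n_e, topology$n_i)
  w <- stacked_weights(topology)

  step <- input_delivery_steps(input_spikes$time, dt, n_steps)
  keep <- step <= n_steps
  o <- order(step[keep], input_spikes$neuron[keep])
  in_step <- step[keep][o]
  in_id <- input_spikes$neuron[keep][o]

  if (engine == "cpp") {
    res <- .run_liquid_cpp(w$w_in, w$w_exc, w$w_inh, in_step, in_id,
                           n_steps, dt, pop)
  } else {
    res <- run_liquid_r(w, in_step, in_id, n_steps, dt, pop)
  }
  spike_record(res$neuron, res$time, duration = T,
               n_neurons = topology$n_e + topology$n_i)
}

# Pure-R engine: composes the exported per-step operations in the documented
# order. Arithmetic matches the compiled engine expression-for-expression.
run_liquid_r <- function(w, in_step, in_id, n_steps, dt, pop) {
  n_e <- pop$n_e
  state <- neuron_state(pop)
  fired_e_prev <- integer(0)
  fired_i_prev <- integer(0)
  out_neuron <- vector("list", n_steps)
  out_time <- vector("list", n_steps)
  ptr <- 1L
  n_in <- length(in_step)
  for (k in seq_len(n_steps)) {
    t_k <- k * dt
    while (ptr <= n_in && in_step[ptr] == k) {
      state$g_e <- state$g_e + w$w_in[, in_id[ptr]]
      ptr <- ptr + 1L
    }
    state <- deliver_spikes(state, w$w_exc, w$w_inh,
                            fired_e_prev, fired_i_prev)
    state <- decay_conductances(state, pop, dt)
    state <- integrate_membrane(state, pop, dt, t_k)
    res <- threshold_and_reset(state, pop, t_k)
    state <- res$state
    fired <- res$fired
    fired_e_prev <- fired[fired <= n_e]
    fired_i_prev <- fired[fired > n_e] - n_e
    if (length(fired)) {
      out_neuron[[k]] <- fired
      out_time[[k]] <- rep(t_k, length(fired))
    }
  }
  list(neuron = unlist(out_neuron), time = unlist(out_time))
}

#' Simulate an ensemble of liquids
#'
#' Each member liquid receives the full input record through its own input
#' mask and is simulated independently (the liquids share no connections).
#'
#' @param ensemble a [build_ensemble()] topology.
#' @inheritParams run_liquid
#' @return an object of class `ensemble_spikes`: a list of [spike_record()]s,
#'   one per liquid, in ensemble order, with attribute `ensemble` sizes.
#' @export
run_ensemble <- function(ensemble, input_spikes, T = input_spikes$duration,
                         dt = 0.5, params = neuron_params(),
                         engine = c("cpp", "r")) {
  stopifnot(inherits(ensemble, "ensemble_topology"))
  engine <- match.arg(engine)
  records <- lapply(ensemble$liquids, run_liquid, input_spikes = input_spikes,
                    T = T, dt = dt, params = params, engine = engine)
  structure(records, class = "ensemble_spikes")
}
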