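# Independent reference implementations used as oracles. Deliberately naive:
# scalar loops over neurons and steps, no vectorization, no reuse of the
# package's engine code paths.

# Naive per-neuron per-step simulator following the documented step contract:
# deliver (input spikes of this step, then E spikes of the previous step,
# then I spikes), decay, integrate with frozen conductances, threshold.
naive_run_liquid <- function(topology, input_spikes, T, dt,
                             params = neuron_params()) {
  n_e <- topology$n_e
  n_i <- topology$n_i
  n <- n_e + n_i
  n_steps <- round(T / dt)

  get_p <- function(i, e, i_) if (i <= n_e) e else i_
  w_in <- rbind(topology$weights$in_e, matrix(0, n_i, topology$n_inputs))
  w_exc <- rbind(topology$weights$e_e, topology$weights$e_i)
  w_inh <- rbind(topology$weights$i_e, topology$weights$i_i)

  v <- numeric(n)
  ge <- numeric(n)
  gi <- numeric(n)
  ref <- numeric(n)
  for (i in 1:n) v[i] <- get_p(i, params$e_rest_e, params$e_rest_i)

  # bin input spikes: spike during step k delivered at start of step k + 1
  in_step <- integer(length(input_spikes$time))
  for (s in seq_along(input_spikes$time)) {
    tt <- input_spikes$time[s]
    in_step[s] <- if (tt <= 0) 1L else as.integer(ceiling(tt / dt - 1e-9)) + 1L
  }
  ord <- order(in_step, input_spikes$neuron)

  prev_fired <- integer(0)
  out_n <- integer(0)
  out_t <- numeric(0)
  for (k in 1:n_steps) {
    t_k <- k * dt
    for (s in ord) {
      if (in_step[s] == k) {
        j <- input_spikes$neuron[s]
        for (i in 1:n) ge[i] <- ge[i] + w_in[i, j]
      }
    }
    for (j in prev_fired[prev_fired <= n_e]) {
      for (i in 1:n) ge[i] <- ge[i] + w_exc[i, j]
    }
    for (j in prev_fired[prev_fired > n_e]) {
      for (i in 1:n) gi[i] <- gi[i] + w_inh[i, j - n_e]
    }
    for (i in 1:n) {
      ge[i] <- ge[i] * exp(-dt / params$tau_ge)
      gi[i] <- gi[i] * exp(-dt / params$tau_gi)
    }
    for (i in 1:n) {
      if (t_k <= ref[i]) next
      tau <- get_p(i, params$tau_mem_e, params$tau_mem_i)
      er <- get_p(i, params$e_rest_e, params$e_rest_i)
      denom <- (1 + ge[i]) + gi[i]
      vinf <- ((er + ge[i] * params$e_exc) + gi[i] * params$e_inh) / denom
      v[i] <- vinf + (v[i] - vinf) * exp(-(dt * denom) / tau)
    }
    fired <- integer(0)
    for (i in 1:n) {
      if (t_k <= ref[i]) next
      th <- get_p(i, params$thresh_e, params$thresh_i)
      if (v[i] >= th) {
        v[i] <- get_p(i, params$v_reset_e, params$v_reset_i)
        ref[i] <- t_k + get_p(i, params$t_refrac_e, params$t_refrac_i)
        fired <- c(fired, i)
        out_n <- c(out_n, i)
        out_t <- c(out_t, t_k)
      }
    }
    prev_fired <- fired
  }
  spike_record(out_n, out_t, duration = T, n_neurons = n)
}

# Hand-wire a tiny liquid with explicit weight matrices (masks inferred).
hand_liquid <- function(n_e, n_i, n_inputs, w_in_e, w_e_e, w_e_i, w_i_e,
                        w_i_i) {
  masks <- lapply(list(in_e = w_in_e, e_e = w_e_e, e_i = w_e_i, i_e = w_i_e,
                       i_i = w_i_i), function(w) (w != 0) * 1)
  structure(list(n_e = n_e, n_i = n_i, n_inputs = n_inputs, masks = masks,
                 weights = list(in_e = w_in_e, e_e = w_e_e, e_i = w_e_i,
                                i_e = w_i_e, i_i = w_i_i),
                 spec = connectivity_spec(p_in_e = 0), seed = NA_integer_),
            class = "liquid_topology")
}

# Two-pass recomputation of the discriminant ratio straight from raw states,
# independent of scatter_matrices(): tr(S_w) from squared deviations to class
# means, tr(S_b) from squared distances between class means and global mean.
two_pass_dr <- function(states, labels) {
  states <- as.matrix(states)
  lv <- unique(labels)
  n <- nrow(states)
  gm <- colMeans(states)
  tr_sw <- 0
  tr_sb <- 0
  for (cl in lv) {
    X <- states[labels == cl, , drop = FALSE]
    nk <- nrow(X)
    mu <- colMeans(X)
    dev2 <- sum(sweep(X, 2, mu)^2)
    tr_sw <- tr_sw + (nk / n) * dev2 / (nk - 1)
    tr_sb <- tr_sb + (nk / n) * sum((mu - gm)^2)
  }
  tr_sb / tr_sw
}

# Small deterministic stimulus helpers.
const_channel_input <- function(p, channels, n_steps, dt = 0.5, seed = 1) {
  encode_channels(channel_stimulus(matrix(p, channels, n_steps), dt = dt),
                  seed = seed)
}
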