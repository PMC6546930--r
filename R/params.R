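#' Neuron parameters of the liquid
#'
#' Parameters of the conductance-based leaky integrate-and-fire model used for
#' both liquid populations. The membrane obeys
#' \deqn{\tau \frac{dV}{dt} = (E_{rest} - V) + g_e (E_{exc} - V) + g_i (E_{inh} - V)}
#' with dimensionless synaptic conductances that jump on presynaptic spikes and
#' decay exponentially, \eqn{\tau_{g} \dot g = -g}. A neuron spikes when `V`
#' reaches its population threshold at the end of a step, is reset, and stays
#' idle for its refractory period.
#'
#' Defaults follow the cortical-microcircuit parameterization used throughout
#' this package: thresholds -52/-40 mV and rest -65/-60 mV for the excitatory/
#' inhibitory populations, conductance decay constants 1/2 ms. Values marked
#' `[assumption]` below are not pinned by that configuration and follow the
#' standard conductance-LIF formulation of Diehl & Cook:
#' membrane time constants 100/10 ms, reversal potentials 0/-100 mV,
#' refractory periods 5/2 ms, and reset equal to the rest potential.
#'
#' @param tau_mem_e,tau_mem_i membrane time constants, ms `[assumption]`.
#' @param e_rest_e,e_rest_i resting potentials, mV.
#' @param thresh_e,thresh_i spike thresholds, mV.
#' @param e_exc,e_inh excitatory/inhibitory reversal potentials, mV
#'   `[assumption]`.
#' @param v_reset_e,v_reset_i post-spike reset potentials, mV (default: the
#'   population rest potential) `[assumption]`.
#' @param t_refrac_e,t_refrac_i refractory durations, ms `[assumption]`.
#' @param tau_ge,tau_gi conductance decay time constants, ms.
#' @return an object of class `neuron_params`.
#' @examples
#' p <- neuron_params()
#' p$thresh_e
#' @export
neuron_params <- function(tau_mem_e = 100, tau_mem_i = 10,
                          e_rest_e = -65, e_rest_i = -60,
                          thresh_e = -52, thresh_i = -40,
                          e_exc = 0, e_inh = -100,
                          v_reset_e = e_rest_e, v_reset_i = e_rest_i,
                          t_refrac_e = 5, t_refrac_i = 2,
                          tau_ge = 1, tau_gi = 2) {
  p <- list(tau_mem_e = tau_mem_e, tau_mem_i = tau_mem_i,
            e_rest_e = e_rest_e, e_rest_i = e_rest_i,
            thresh_e = thresh_e, thresh_i = thresh_i,
            e_exc = e_exc, e_inh = e_inh,
            v_reset_e = v_reset_e, v_reset_i = v_reset_i,
            t_refrac_e = t_refrac_e, t_refrac_i = t_refrac_i,
            tau_ge = tau_ge, tau_gi = tau_gi)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop_liquidens(sprintf("neuron_params: '%s' must be a finite scalar", nm),
                     "invalid_params")
  }
  if (p$tau_mem_e <= 0 || p$tau_mem_i <= 0 || p$tau_ge <= 0 || p$tau_gi <= 0)
    stop_liquidens("neuron_params: time constants must be > 0", "invalid_params")
  if (p$thresh_e <= p$e_rest_e || p$thresh_i <= p$e_rest_i)
    stop_liquidens("neuron_params: threshold must exceed rest potential",
                   "invalid_params")
  if (p$e_exc <= p$thresh_e)
    stop_liquidens("neuron_params: e_exc must exceed thresh_e", "invalid_params")
  if (p$e_inh > p$e_rest_i)
    stop_liquidens("neuron_params: e_inh must not exceed e_rest_i",
                   "invalid_params")
  if (p$t_refrac_e < 0 || p$t_refrac_i < 0)
    stop_liquidens("neuron_params: refractory durations must be >= 0",
                   "invalid_params")
  structure(p, class = "neuron_params")
}

#' Expand population parameters to per-neuron vectors
#'
#' The liquid stacks `n_e` excitatory neurons (indices `1..n_e`) ahead of
#' `n_i` inhibitory neurons. The simulator operates on per-neuron parameter
#' vectors; this helper produces them from a [neuron_params()] object.
#'
#' @param params a [neuron_params()] object.
#' @param n_e,n_i population sizes.
#' @return list of per-neuron vectors `tau_mem`, `e_rest`, `thresh`,
#'   `v_reset`, `t_refrac` plus scalars `tau_ge`, `tau_gi`, `e_exc`, `e_inh`.
#' @export
population_params <- function(params, n_e, n_i) {
  stopifnot(inherits(params, "neuron_params"), is_count(n_e), is_count(n_i))
  rep2 <- function(e, i) c(rep(e, n_e), rep(i, n_i))
  list(tau_mem  = rep2(params$tau_mem_e, params$tau_mem_i),
       e_rest   = rep2(params$e_rest_e, params$e_rest_i),
       thresh   = rep2(params$thresh_e, params$thresh_i),
       v_reset  = rep2(params$v_reset_e, params$v_reset_i),
       t_refrac = rep2(params$t_refrac_e, params$t_refrac_i),
       tau_ge = params$tau_ge, tau_gi = params$tau_gi,
       e_exc = params$e_exc, e_inh = params$e_inh,
       n_e = as.integer(n_e), n_i = as.integer(n_i))
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  cat(sprintf("  E: rest %g mV, thresh %g mV, reset %g mV, tau_m %g ms, refrac %g ms\n",
              x$e_rest_e, x$thresh_e, x$v_reset_e, x$tau_mem_e, x$t_refrac_e))
  cat(sprintf("  I: rest %g mV, thresh %g mV, reset %g mV, tau_m %g ms, refrac %g ms\n",
              x$e_rest_i, x$thresh_i, x$v_reset_i, x$tau_mem_i, x$t_refrac_i))
  cat(sprintf("  reversal: e_exc %g mV, e_inh %g mV; tau_ge %g ms, tau_gi %g ms\n",
              x$e_exc, x$e_inh, x$tau_ge, x$tau_gi))
  invisible(x)
}

#' Create a fresh neuron state
#'
#' All membranes at their rest potential, conductances at zero, no neuron
#' refractory: the initial condition of every simulation.
#'
#' @param pop per-neuron parameters from [population_params()].
#' @return an object of class `neuron_state` with fields `v`, `g_e`, `g_i`,
#'   `refractory_until` (each a vector over neurons).
#' @export
neuron_state <- function(pop) {
  n <- pop$n_e + pop$n_i
  structure(list(v = pop$e_rest, g_e = numeric(n), g_i = numeric(n),
                 refractory_until = numeric(n)),
            class = "neuron_state")
}
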