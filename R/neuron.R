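#' Configuration of the stochastically spiking neuron
#'
#' Membrane dynamics are a linear sum of exponentially decaying post-synaptic
#' potentials (PSPs); spiking is an inhomogeneous Bernoulli process whose
#' per-step probability depends on the gain [gain()] and the refractory state
#' [refractory_factor()].
#'
#' The intrinsic-plasticity target mean `mu_goal` must be small relative to
#' the maximal rate imposed by the absolute refractory period
#' (`mu_goal <= 0.1 * 1000 / tau_abs` Hz), so that the untruncated exponential
#' is a valid target for the rate distribution.
#'
#' @param u_rest Resting potential (mV).
#' @param tau_m Excitatory PSP decay constant (ms).
#' @param tau_gaba Inhibitory PSP decay constant (ms).
#' @param psp_amplitude PSP jump per presynaptic spike, per unit weight (mV).
#' @param tau_abs Absolute refractory period (ms); at least `dt`.
#' @param tau_refr Relative refractory period (ms).
#' @param dt Integration step (ms).
#' @param mu_goal Target mean firing rate of intrinsic plasticity (Hz).
#' @return An object of class `neuron_config`.
#' @export
neuron_config <- function(u_rest = -70, tau_m = 10, tau_gaba = 10,
                          psp_amplitude = 1, tau_abs = 3, tau_refr = 10,
                          dt = 1, mu_goal = 5) {
  vals <- c(tau_m = tau_m, tau_gaba = tau_gaba, psp_amplitude = psp_amplitude,
            tau_abs = tau_abs, tau_refr = tau_refr, dt = dt, mu_goal = mu_goal)
  if (any(!is.finite(c(u_rest, vals))) || any(vals <= 0))
    stop("all neuron time constants, amplitudes, dt and mu_goal must be finite and > 0")
  if (tau_abs < dt) stop("tau_abs must be >= dt")
  if (mu_goal > 0.1 * 1000 / tau_abs)
    stop(sprintf("mu_goal must be <= 0.1/tau_abs = %.1f Hz for the exponential-rate target to hold",
                 0.1 * 1000 / tau_abs))
  structure(list(u_rest = u_rest, tau_m = tau_m, tau_gaba = tau_gaba,
                 psp_amplitude = psp_amplitude, tau_abs = tau_abs,
                 tau_refr = tau_refr, dt = dt, mu_goal = mu_goal),
            class = "neuron_config")
}

#' Fresh neuron state
#'
#' @param n_exc Number of excitatory afferent synapses.
#' @param n_inh Number of inhibitory afferent synapses.
#' @param cfg A [neuron_config()].
#' @return An object of class `neuron_state` with per-synapse PSP traces,
#'   the time of the last emitted spike (`-Inf` for "never"), the current
#'   membrane potential `u` and the current time `t` (ms).
#' @export
neuron_state <- function(n_exc, n_inh = 0, cfg = neuron_config()) {
  structure(list(trace_exc = numeric(n_exc), trace_inh = numeric(n_inh),
                 t_last_spike = -Inf, u = cfg$u_rest, t = 0),
            class = "neuron_state")
}

#' Refractory recovery factor
#'
#' Zero during the absolute refractory period, then saturating recovery
#' \eqn{R(\Delta) = (\Delta - \tau_{abs}) / (\tau_{refr} + \Delta - \tau_{abs})},
#' which increases monotonically to 1. A neuron that has never fired has
#' `t_since_spike = Inf` and `R = 1`.
#'
#' @param t_since_spike Time since the last spike (ms); `Inf` for "never".
#'   Vectorized.
#' @param cfg A [neuron_config()].
#' @return Factor(s) in `[0, 1]`.
#' @export
refractory_factor <- function(t_since_spike, cfg = neuron_config()) {
  if (any(is.na(t_since_spike)) || any(t_since_spike < 0))
    stop("t_since_spike must be nonnegative (Inf for 'never fired')")
  d <- t_since_spike - cfg$tau_abs
  ifelse(t_since_spike == Inf, 1, ifelse(d < 0, 0, d / (cfg$tau_refr + d)))
}

#' One membrane integration step
#'
#' Decays all PSP traces (excitatory by `exp(-dt/tau_m)`, inhibitory by
#' `exp(-dt/tau_gaba)`), adds `psp_amplitude` to the trace of every synapse
#' that fired this step, and recomputes the membrane potential
#' \eqn{u = u_{rest} + \sum_i w^{exc}_i x^{exc}_i - \sum_j w^{inh}_j x^{inh}_j}.
#'
#' @param state A [neuron_state()].
#' @param exc_spikes Binary vector of excitatory afferent spikes this step.
#' @param inh_spikes Binary vector of inhibitory afferent spikes this step.
#' @param w_exc,w_inh Nonnegative weight vectors matching the spike vectors.
#' @param cfg A [neuron_config()].
#' @return The updated state (time advanced by `dt`).
#' @export
membrane_update <- function(state, exc_spikes, inh_spikes = numeric(0),
                            w_exc, w_inh = numeric(0), cfg = neuron_config()) {
  if (length(exc_spikes) != length(w_exc) || length(inh_spikes) != length(w_inh))
    stop("spike vectors and weight vectors must have matching lengths")
  if (any(w_exc < 0) || any(w_inh < 0)) stop("weights must be nonnegative")
  state$trace_exc <- state$trace_exc * exp(-cfg$dt / cfg$tau_m) +
    cfg$psp_amplitude * as.numeric(exc_spikes)
  if (length(inh_spikes))
    state$trace_inh <- state$trace_inh * exp(-cfg$dt / cfg$tau_gaba) +
      cfg$psp_amplitude * as.numeric(inh_spikes)
  state$u <- cfg$u_rest + sum(w_exc * state$trace_exc) -
    (if (length(w_inh)) sum(w_inh * state$trace_inh) else 0)
  state$t <- state$t + cfg$dt
  state
}

#' Draw a spike for the current step
#'
#' Per-step spike probability uses the exact exponential form
#' \eqn{P = 1 - e^{-R\, g(u)\, \Delta t}} (never exceeding 1), where `R` is the
#' refractory factor at the time since the last spike. On a spike,
#' `t_last_spike` is set to the current time.
#'
#' @param u Membrane potential (mV).
#' @param state A [neuron_state()] (supplies the time since the last spike).
#' @param p [gain_params()].
#' @param cfg [neuron_config()].
#' @return A list with `spike` (0 or 1) and the updated `state`.
#' @export
spike_draw <- function(u, state, p, cfg = neuron_config()) {
  g <- gain(u, p)
  if (g * cfg$dt / 1000 > 0.2)
    warning(sprintf("g*dt = %.2f: integration step too coarse for this rate", g * cfg$dt / 1000))
  r <- refractory_factor(state$t - state$t_last_spike, cfg)
  prob <- 1 - exp(-r * g * cfg$dt / 1000)
  spike <- as.integer(stats::runif(1) < prob)
  if (spike == 1L) state$t_last_spike <- state$t
  list(spike = spike, state = state)
}
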