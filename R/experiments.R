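#' Preconfigured experiments
#'
#' Ready-made [experiment_config()]s with the package's calibrated study
#' conditions for each benchmark. All of them share the spiking-task neuron
#' settings (PSP amplitude 10 mV per unit weight, IP target rate 10 Hz) and
#' the synaptic-scaling scheme (L1 total 10 with a per-synapse saturation
#' bound of five times the uniform weight, the hard upper limit of additive
#' STDP).
#'
#' * `bars_experiment_config`: single neuron learning one bar from rate-coded
#'   bar images (by default the hard variant: every sample contains exactly 4
#'   distinct bars on a 5x5 grid, so single-bar samples never occur).
#' * `bars_corr_experiment_config`: bars encoded purely in pairwise spike
#'   correlations (all channels at the same mean rate); STDP windows are
#'   symmetrized (`tau_plus = tau_minus = 20` ms) as appropriate for
#'   spike-spike correlation learning, with depression slightly dominant.
#' * `population_experiment_config`: 10 laterally inhibited neurons on the
#'   10x10 2-px-wide bars task, whose 10-bar basis matches the population
#'   size.
#' * `demix_spike_experiment_config`: the spike-based two-source demixing
#'   problem with on/off channels replicated over 25 synapses each.
#'
#' @param n_samples Sample presentations.
#' @param seed RNG seed.
#' @param bars A [bars_config()] for the bars variants.
#' @param demix A [demix_config()] for the demixing variant.
#' @param ip_mode Intrinsic-plasticity mode (see [experiment_config()]).
#' @param n_neurons Population size.
#' @param nu,c Mean rate (Hz) and pairwise correlation of the correlation
#'   encoding.
#' @param ... Further arguments passed to [experiment_config()] (e.g.
#'   `gain_init`, `mean_rate`, `record_every`).
#' @return An [experiment_config()].
#' @name experiment_presets
NULL

spiking_task_neuron <- function() {
  neuron_config(psp_amplitude = 10, mu_goal = 10)
}

spiking_task_scaling <- function(n_syn, W_total = 10) {
  scaling_config(W_total = W_total, w_max = 5 * W_total / n_syn)
}

#' @rdname experiment_presets
#' @export
bars_experiment_config <- function(n_samples = 3000, seed = 1,
                                   bars = bars_config(grid = 5,
                                                      mode = "exactly_k",
                                                      k = 4),
                                   ip_mode = "full", ...) {
  task <- bars_task(bars)
  experiment_config(task, n_samples = n_samples, seed = seed,
                    neuron = spiking_task_neuron(),
                    ip = ip_config(mu_goal = 10),
                    stdp = stdp_params(),
                    scaling = spiking_task_scaling(task$n_syn),
                    ip_mode = ip_mode, ...)
}

#' @rdname experiment_presets
#' @export
bars_corr_experiment_config <- function(n_samples = 3000, seed = 1,
                                        bars = bars_config(grid = 10,
                                                           bar_width = 2,
                                                           mode = "exactly_k",
                                                           k = 2),
                                        nu = 20, c = 0.5,
                                        ip_mode = "full", ...) {
  task <- bars_corr_task(bars, nu = nu, c = c)
  experiment_config(task, n_samples = n_samples, seed = seed,
                    neuron = spiking_task_neuron(),
                    ip = ip_config(mu_goal = 10),
                    stdp = stdp_params(A_plus = 0.01, A_minus = 0.0105,
                                       tau_plus = 20, tau_minus = 20),
                    scaling = spiking_task_scaling(task$n_syn),
                    ip_mode = ip_mode, ...)
}

#' @rdname experiment_presets
#' @export
population_experiment_config <- function(n_samples = 6000, seed = 1,
                                         bars = bars_config(grid = 10,
                                                            bar_width = 2,
                                                            mode = "independent_p",
                                                            p = 0.1),
                                         n_neurons = 10, ip_mode = "full",
                                         ...) {
  task <- bars_task(bars)
  experiment_config(task, n_samples = n_samples, seed = seed,
                    neuron = spiking_task_neuron(),
                    ip = ip_config(mu_goal = 10),
                    stdp = stdp_params(),
                    scaling = spiking_task_scaling(task$n_syn),
                    population = list(n_neurons = n_neurons,
                                      W_total_inh = 50, inh_stdp_gain = 5,
                                      jitter_var = c(0.1, 5, 0.2)),
                    ip_mode = ip_mode, ...)
}

#' @rdname experiment_presets
#' @export
demix_spike_experiment_config <- function(n_samples = 3000, seed = 1,
                                          demix = demix_config(),
                                          ip_mode = "full", ...) {
  task <- demix_spike_task(demix)
  experiment_config(task, n_samples = n_samples, seed = seed,
                    neuron = spiking_task_neuron(),
                    ip = ip_config(mu_goal = 10),
                    stdp = stdp_params(),
                    scaling = spiking_task_scaling(task$n_syn, W_total = 30),
                    ip_mode = ip_mode, ...)
}

#' Assign a receptive field to its best-matching bar
#'
#' If [count_bars()] finds exactly one bar, that bar is the assignment;
#' otherwise the template with the highest weight concentration (fraction of
#' total weight mass on the bar's pixels, corrected for bar size) is chosen.
#' Used to count how many distinct basis elements a population recovered.
#'
#' @param rf Weight map (matrix).
#' @param cfg The task's [bars_config()].
#' @return A list with `bar` (template id), `exact` (TRUE if the RF contains
#'   exactly that one bar by [count_bars()]) and `overlap` (weight fraction
#'   on the assigned bar).
#' @export
assign_rf_to_bar <- function(rf, cfg) {
  cb <- count_bars(rf, cfg)
  tmpl <- bar_templates(cfg)
  ov <- vapply(tmpl, function(tm) sum(abs(rf) * tm), numeric(1)) /
    max(sum(abs(rf)), .Machine$double.eps)
  if (cb$count == 1L) {
    list(bar = cb$bars, exact = TRUE, overlap = ov[cb$bars])
  } else {
    b <- which.max(ov)
    list(bar = b, exact = FALSE, overlap = ov[b])
  }
}

#' Distinct bars recovered by a population
#'
#' Applies [assign_rf_to_bar()] to each neuron's final feedforward weights
#' and counts the distinct assigned basis elements.
#'
#' @param trace An `ica_trace` from a bars population run.
#' @return A list with `n_distinct`, `assignments` (per-neuron bar ids) and
#'   `exact` (per-neuron logical).
#' @export
population_distinct_bars <- function(trace) {
  cfg <- trace$cfg$task$bars_cfg
  n <- nrow(trace$model$W)
  asg <- integer(n); exact <- logical(n)
  for (i in seq_len(n)) {
    rf <- matrix(trace$model$W[i, ], cfg$grid, cfg$grid)
    a <- assign_rf_to_bar(rf, cfg)
    asg[i] <- a$bar; exact[i] <- a$exact
  }
  list(n_distinct = length(unique(asg)), assignments = asg, exact = exact)
}
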