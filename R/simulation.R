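#' Task constructors
#'
#' A task bundles the input geometry with a sampler that draws one stimulus
#' presentation. `bars_task` encodes bar images as per-pixel Poisson rates;
#' `bars_corr_task` encodes them purely in pairwise spike correlations (all
#' channels share the same mean rate; the pixels of the sample's bars form
#' one equicorrelated set); `demix_spike_task` draws a rotated Laplacian
#' source pair, splits it into on/off channels and replicates each channel
#' over several independent synapses; `image_task` presents precomputed
#' on/off rate maps (e.g. from [preprocess_image_patches()]), with the on and
#' off populations scaled independently.
#'
#' @param cfg A [bars_config()] (bars tasks) or [demix_config()].
#' @param nu Common mean rate of the correlation encoding (Hz).
#' @param c Pairwise correlation of bar-pixel spike indicators.
#' @param dt Bin width (ms) of the correlation encoding.
#' @param patches List of `list(on=, off=)` rate maps.
#' @param sample_duration Presentation time (ms) for `image_task`.
#' @return An object of class `ica_task`: fields `n_syn`, `duration`,
#'   `scaling_masks` (NULL or list of index vectors) and `sample()`, a
#'   closure returning `list(rates=)` or `list(spikes=)` plus metadata.
#' @name tasks
NULL

#' @rdname tasks
#' @export
bars_task <- function(cfg = bars_config()) {
  force(cfg)
  structure(list(
    name = "bars", n_syn = cfg$grid^2, duration = cfg$sample_duration,
    scaling_masks = NULL, bars_cfg = cfg,
    sample = function() {
      bs <- bars_sample(cfg)
      list(rates = as.numeric(bars_to_rates(bs$grid, cfg)), bars = bs$bars)
    }), class = "ica_task")
}

#' @rdname tasks
#' @export
bars_corr_task <- function(cfg = bars_config(grid = 10, bar_width = 2,
                                             mode = "exactly_k", k = 2),
                           nu = 20, c = 0.5, dt = 1) {
  force(cfg)
  sol <- solve_dichotomous_gaussian(nu, c, dt)
  n_syn <- cfg$grid^2
  structure(list(
    name = "bars_corr", n_syn = n_syn, duration = cfg$sample_duration,
    scaling_masks = NULL, bars_cfg = cfg, nu = nu, c = c,
    sample = function() {
      bs <- bars_sample(cfg)
      members <- which(bs$grid == 1L)
      spec <- structure(list(nu = nu, c = c,
                             member_sets = if (length(members) > 1)
                               list(members) else list(),
                             n_channels = n_syn, dt = dt,
                             gamma = sol$gamma, lam = sol$lam),
                        class = "correlation_spec")
      list(spikes = correlated_trains(spec, cfg$sample_duration),
           bars = bs$bars)
    }), class = "ica_task")
}

#' @rdname tasks
#' @export
demix_spike_task <- function(cfg = demix_config()) {
  force(cfg)
  spc <- cfg$synapses_per_channel
  structure(list(
    name = "demix_spike", n_syn = 4L * spc, duration = cfg$sample_duration,
    scaling_masks = NULL, demix_cfg = cfg,
    sample = function() {
      s <- as.numeric(sample_laplace_pair(1))
      ch <- onoff_encode(mix_rotate(s, cfg$theta)) * cfg$rate_scale
      list(rates = rep(ch, each = spc), source = s)
    }), class = "ica_task")
}

#' @rdname tasks
#' @export
image_task <- function(patches, sample_duration = 200) {
  stopifnot(length(patches) >= 1)
  npix <- length(patches[[1]]$on)
  structure(list(
    name = "image", n_syn = 2L * npix, duration = sample_duration,
    scaling_masks = list(seq_len(npix), npix + seq_len(npix)),
    sample = function() {
      p <- patches[[sample.int(length(patches), 1)]]
      list(rates = c(as.numeric(p$on), as.numeric(p$off)))
    }), class = "ica_task")
}

#' Experiment configuration
#'
#' Bundles the task, neuron, plasticity and scaling settings of one run.
#' Exactly one intrinsic-plasticity mode is active: `"full"` (the
#' three-parameter KL-gradient rule), `"fixed"` (gain frozen at
#' `gain_init` — the ablation control), or `"mean_rate"` (the
#' threshold-only control rule).
#'
#' @param task An `ica_task`.
#' @param n_samples Number of sample presentations.
#' @param seed RNG seed of the run.
#' @param neuron A [neuron_config()].
#' @param gain_init Initial [gain_params()].
#' @param ip An [ip_config()].
#' @param ip_mode `"full"`, `"fixed"` or `"mean_rate"`.
#' @param mean_rate A [mean_rate_ip_config()] (mean-rate mode).
#' @param stdp An [stdp_params()].
#' @param stdp_on Enable synaptic plasticity.
#' @param scaling A [scaling_config()] for the excitatory weights.
#' @param population `NULL` for a single neuron, else a list with
#'   `n_neurons`, `W_total_inh` (scaling target of each neuron's incoming
#'   lateral weights), `inh_stdp_gain` (amplitude factor of the faster
#'   inhibitory STDP), and `jitter_var` (variances of the uniform jitter on
#'   the initial `r0`, `u0`, `u_alpha`).
#' @param record_every Samples between weight/gain snapshots.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(task, n_samples, seed = 1,
                              neuron = neuron_config(),
                              gain_init = gain_params(),
                              ip = ip_config(mu_goal = neuron$mu_goal),
                              ip_mode = c("full", "fixed", "mean_rate"),
                              mean_rate = mean_rate_ip_config(r_goal = neuron$mu_goal),
                              stdp = stdp_params(),
                              stdp_on = TRUE,
                              scaling = scaling_config(W_total = 100),
                              population = NULL,
                              record_every = 50) {
  ip_mode <- match.arg(ip_mode)
  stopifnot(inherits(task, "ica_task"), n_samples >= 1)
  if (!is.null(population)) {
    stopifnot(population$n_neurons >= 1)
    population$inh_stdp_gain <- population$inh_stdp_gain %||% 5
    population$W_total_inh <- population$W_total_inh %||% 100
    population$jitter_var <- population$jitter_var %||% c(0.1, 5, 0.2)
    if (population$n_neurons > 1 && population$inh_stdp_gain <= 1)
      warning("inhibitory STDP should adapt faster than the feedforward synapses (inh_stdp_gain > 1) for efficient decorrelation")
  }
  structure(list(task = task, n_samples = as.integer(n_samples),
                 seed = as.integer(seed), neuron = neuron,
                 gain_init = gain_init, ip = ip, ip_mode = ip_mode,
                 mean_rate = mean_rate, stdp = stdp, stdp_on = stdp_on,
                 scaling = scaling, population = population,
                 record_every = as.integer(record_every)),
            class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mutable model: weights, gains and engine state for one run
init_model <- function(cfg) {
  n_syn <- cfg$task$n_syn
  n <- if (is.null(cfg$population)) 1L else as.integer(cfg$population$n_neurons)
  masks <- cfg$task$scaling_masks %||% list(seq_len(n_syn))
  W <- matrix(stats::runif(n * n_syn), n, n_syn)
  for (i in seq_len(n)) W[i, ] <- scale_weights(W[i, ], cfg$scaling, masks)
  Winh <- matrix(0, n, n)
  if (n > 1) {
    Winh <- matrix(stats::runif(n * n), n, n)
    diag(Winh) <- 0
    for (i in seq_len(n))
      Winh[i, ] <- Winh[i, ] * cfg$population$W_total_inh / sum(Winh[i, ])
  }
  g0 <- cfg$gain_init
  gains <- matrix(rep(c(g0$r0, g0$u0, g0$u_alpha), each = n), n, 3)
  if (n > 1) {
    hw <- sqrt(3 * cfg$population$jitter_var)
    for (j in 1:3)
      gains[, j] <- gains[, j] + stats::runif(n, -hw[j], hw[j])
    gains[, 1] <- pmax(gains[, 1], 0.1)
    gains[, 3] <- pmax(gains[, 3], 0.1)
  }
  mdl <- new.env(parent = emptyenv())
  mdl$W <- W
  mdl$Winh <- Winh
  mdl$gains <- gains
  mdl$masks <- masks
  mdl$n_neurons <- n
  mdl$st <- list(x_exc = numeric(n_syn), x_inh = numeric(n),
                 delta_spike = rep(1e12, n), pre_trace = numeric(n_syn),
                 pre_snap = matrix(0, n, n_syn), inh_pre = numeric(n),
                 inh_snap = matrix(0, n, n), y_post = numeric(n),
                 y_slow = numeric(n), r_bar = numeric(n))
  mdl$ecfg <- engine_config(cfg)
  mdl$cfg <- cfg
  mdl$clamp_count <- 0L
  class(mdl) <- "spiking_model"
  mdl
}

engine_config <- function(cfg) {
  nc <- cfg$neuron
  ip_mode <- switch(cfg$ip_mode, fixed = 0L, full = 1L, mean_rate = 2L)
  list(dt = nc$dt, tau_m = nc$tau_m, tau_gaba = nc$tau_gaba,
       tau_abs = nc$tau_abs, tau_refr = nc$tau_refr, u_rest = nc$u_rest,
       psp_amplitude = nc$psp_amplitude, mu_goal = cfg$ip$mu_goal,
       ip_mode = ip_mode, eta_ip = cfg$ip$eta_ip,
       r0_floor = 1e-6 * cfg$gain_init$r0,
       ua_floor = 1e-6 * cfg$gain_init$u_alpha,
       eta_mr = cfg$mean_rate$eta_mr, tau_r = cfg$mean_rate$tau_r,
       r_goal = cfg$mean_rate$r_goal,
       stdp_on = cfg$stdp_on,
       stdp_mode = switch(cfg$stdp$mode, nearest = 0L, all_to_all = 1L,
                          triplet = 2L),
       A_plus = cfg$stdp$A_plus, A_minus = cfg$stdp$A_minus,
       tau_plus = cfg$stdp$tau_plus, tau_minus = cfg$stdp$tau_minus,
       A3_plus = if (cfg$stdp$mode == "triplet") cfg$stdp$A3_plus else 0,
       tau_y = cfg$stdp$tau_y,
       w_max = cfg$scaling$w_max %||% Inf,
       inh_stdp_gain = if (is.null(cfg$population)) 1
                       else cfg$population$inh_stdp_gain,
       inh_plastic = cfg$stdp_on && !is.null(cfg$population) &&
         cfg$population$n_neurons > 1)
}

#' Present one stimulus sample to the model
#'
#' Simulates `duration/dt` steps of the coupled neuron/plasticity dynamics
#' (membrane integration, intrinsic plasticity, stochastic spiking, STDP,
#' lateral inhibition), then clips the weights at zero and applies synaptic
#' scaling — once per sample, as a homeostatic mechanism operating on a
#' slower timescale than STDP. The model environment is updated in place.
#'
#' @param model A `spiking_model` (from [run_experiment()]'s machinery; see
#'   its `model` field).
#' @param sample A stimulus sample: `list(rates=)` (per-synapse Hz, encoded
#'   as independent Bernoulli bins) or `list(spikes=)` (a binary steps x
#'   synapses matrix). A zero-duration sample leaves every state unchanged.
#' @param record_steps Record per-step membrane potential and gain.
#' @return Invisibly, a list with per-neuron `spike_count`, `mean_g`,
#'   `g_last` and optionally `step_record`.
#' @export
present_sample <- function(model, sample, record_steps = FALSE) {
  cfg <- model$cfg
  spikes <- if (!is.null(sample$spikes)) {
    sample$spikes
  } else {
    poisson_trains(sample$rates, cfg$task$duration, cfg$neuron$dt)
  }
  if (nrow(spikes) == 0) {
    return(invisible(list(spike_count = integer(model$n_neurons),
                          mean_g = numeric(model$n_neurons),
                          g_last = numeric(model$n_neurons))))
  }
  storage.mode(spikes) <- "integer"
  res <- sim_present_sample(spikes, model$W, model$Winh, model$gains,
                            model$st, model$ecfg, record_steps)
  model$clamp_count <- model$clamp_count + res$clamp_count
  if (cfg$stdp_on) {
    W <- clip_nonnegative(model$W)
    for (i in seq_len(model$n_neurons)) {
      Wi <- tryCatch(scale_weights(W[i, ], cfg$scaling, model$masks),
                     error = function(e)
                       stop("neuron ", i, ": ", conditionMessage(e),
                            call. = FALSE))
      W[i, ] <- Wi
    }
    model$W <- W
    if (model$n_neurons > 1) {
      Winh <- clip_nonnegative(model$Winh)
      diag(Winh) <- 0
      rs <- rowSums(Winh)
      if (any(rs <= 0)) stop("dead inhibitory scope during scaling")
      model$Winh <- Winh * (cfg$population$W_total_inh / rs)
    }
  }
  invisible(res)
}

#' Run a learning experiment
#'
#' The experiment engine: initializes weights (uniform, then scaled) and gain
#' parameters, then presents `n_samples` stimuli with [present_sample()],
#' logging per-sample firing rates, instantaneous gains, and periodic weight
#' snapshots. Runs are a pure function of (configuration, seed).
#'
#' @param cfg An [experiment_config()].
#' @param init Optional snapshot to resume from: a list with `W`, `Winh`,
#'   `gains`, `st` (as found in a previous trace's `model` field).
#' @return An object of class `ica_trace`: matrices `rates` (neurons x
#'   samples, Hz), `mean_g`, `g_last`; `snapshots` (list of `sample`, `W`,
#'   `gains`); `sample_meta` (per-sample metadata such as active bar ids);
#'   the final `model`; and the `cfg`.
#' @export
run_experiment <- function(cfg, init = NULL) {
  set.seed(cfg$seed)
  model <- init_model(cfg)
  if (!is.null(init)) {
    for (f in c("W", "Winh", "gains")) if (!is.null(init[[f]]))
      assign(f, init[[f]], envir = model)
    if (!is.null(init$st)) model$st <- init$st
  }
  S <- cfg$n_samples
  n <- model$n_neurons
  rates <- matrix(NA_real_, n, S)
  mean_g <- matrix(NA_real_, n, S)
  g_last <- matrix(NA_real_, n, S)
  snapshots <- list()
  sample_meta <- vector("list", S)
  dur_s <- cfg$task$duration / 1000
  for (k in seq_len(S)) {
    smp <- cfg$task$sample()
    res <- tryCatch(present_sample(model, smp),
                    error = function(e)
                      stop("sample ", k, ": ", conditionMessage(e),
                           call. = FALSE))
    rates[, k] <- res$spike_count / dur_s
    mean_g[, k] <- res$mean_g
    g_last[, k] <- res$g_last
    sample_meta[[k]] <- smp$bars %||% smp$source
    if (k %% cfg$record_every == 0L || k == S) {
      snapshots[[length(snapshots) + 1L]] <-
        list(sample = k, W = model$W, gains = model$gains)
    }
  }
  structure(list(rates = rates, mean_g = mean_g, g_last = g_last,
                 snapshots = snapshots, sample_meta = sample_meta,
                 model = model, cfg = cfg),
            class = "ica_trace")
}

#' Run a laterally inhibited population experiment
#'
#' As [run_experiment()] with a multi-neuron population: all neurons share
#' the afferent layer and are recurrently connected by all-to-all plastic
#' inhibitory synapses (no self-connections; inhibitory STDP runs
#' `inh_stdp_gain` times faster than the feedforward STDP, and the same
#' per-neuron synaptic scaling is applied to the incoming lateral weights).
#' Initial gain parameters are jittered uniformly across neurons. With
#' `n_neurons = 1` this degenerates exactly to [run_experiment()].
#'
#' @inheritParams run_experiment
#' @return An `ica_trace`.
#' @export
run_population <- function(cfg, init = NULL) {
  if (is.null(cfg$population)) stop("cfg$population must be set for run_population")
  run_experiment(cfg, init = init)
}

#' @export
print.ica_trace <- function(x, ...) {
  n <- nrow(x$rates)
  cat(sprintf("ica_trace: task '%s', %d neuron(s), %d samples\n",
              x$cfg$task$name, n, ncol(x$rates)))
  cat(sprintf("  final mean rate(s): %s Hz\n",
              paste(round(rowMeans(x$rates[, max(1, ncol(x$rates) - 99):ncol(x$rates), drop = FALSE]), 2),
                    collapse = ", ")))
  invisible(x)
}

#' Write a trace to tidy CSV files
#'
#' `trace.csv` holds the logged time series in long format
#' (`t_ms`, `neuron`, `variable`, `value`); `weights_final.csv` holds the
#' final feedforward weights (`neuron`, `synapse_id`, `weight`), and, for a
#' population, `weights_inhibitory.csv` the lateral weights.
#'
#' @param trace An `ica_trace`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_trace_csv <- function(trace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  S <- ncol(trace$rates)
  n <- nrow(trace$rates)
  dur <- trace$cfg$task$duration
  t_ms <- rep(seq_len(S) * dur, each = n)
  long <- rbind(
    data.frame(t_ms = t_ms, neuron = rep(seq_len(n), S),
               variable = "rate_hz", value = as.numeric(trace$rates)),
    data.frame(t_ms = t_ms, neuron = rep(seq_len(n), S),
               variable = "g_last_hz", value = as.numeric(trace$g_last)))
  gtab <- do.call(rbind, lapply(trace$snapshots, function(s)
    data.frame(t_ms = rep(s$sample * dur, n), neuron = seq_len(n),
               r0_hz = s$gains[, 1], u0_mv = s$gains[, 2],
               ualpha_mv = s$gains[, 3])))
  p1 <- file.path(dir, "trace.csv")
  p2 <- file.path(dir, "gains.csv")
  p3 <- file.path(dir, "weights_final.csv")
  utils::write.csv(long, p1, row.names = FALSE)
  utils::write.csv(gtab, p2, row.names = FALSE)
  W <- trace$model$W
  utils::write.csv(data.frame(neuron = rep(seq_len(n), ncol(W)),
                              synapse_id = rep(seq_len(ncol(W)), each = n),
                              weight = as.numeric(W)),
                   p3, row.names = FALSE)
  paths <- c(p1, p2, p3)
  if (n > 1) {
    p4 <- file.path(dir, "weights_inhibitory.csv")
    utils::write.csv(as.data.frame(trace$model$Winh), p4, row.names = FALSE)
    paths <- c(paths, p4)
  }
  invisible(paths)
}
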