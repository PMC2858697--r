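#' STDP parameters
#'
#' Pair-based spike-timing dependent plasticity with exponential windows.
#' The default variant uses nearest-neighbor interactions in the
#' presynaptic-centered sense: each presynaptic spike is paired with its
#' nearest preceding postsynaptic spike (depression, amplitude `A_minus`,
#' window `tau_minus`) and its nearest following postsynaptic spike
#' (potentiation, amplitude `A_plus`, window `tau_plus`). For independent
#' Poisson pre/post trains this scheme makes the expected weight drift a
#' BCM-like function of the postsynaptic rate (see [expected_drift_nn()] and
#' [bcm_threshold()]). Alternatives: classical additive all-to-all STDP
#' (`mode = "all_to_all"`, exponential pre/post traces) and a minimal triplet
#' rule (`mode = "triplet"`) whose potentiation is additionally scaled by a
#' slow postsynaptic trace.
#'
#' The defaults place the rule in the "BCM regime": potentiation dominates on
#' the short time scale (`A_plus > A_minus`) while overall depression
#' dominates (`A_minus * tau_minus > A_plus * tau_plus`). For learning
#' spike-spike correlations the time constants are typically shortened and
#' symmetrized (e.g. `tau_plus = tau_minus = 20` ms).
#'
#' @param A_plus Potentiation amplitude (weight units per pairing).
#' @param A_minus Depression amplitude.
#' @param tau_plus Potentiation time constant (ms).
#' @param tau_minus Depression time constant (ms).
#' @param mode One of `"nearest"`, `"all_to_all"`, `"triplet"`.
#' @param A3_plus Triplet-term amplitude (triplet mode).
#' @param tau_y Slow postsynaptic trace time constant (ms, triplet mode).
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(A_plus = 0.01, A_minus = 0.006,
                        tau_plus = 20, tau_minus = 40,
                        mode = c("nearest", "all_to_all", "triplet"),
                        A3_plus = 0.005, tau_y = 100) {
  mode <- match.arg(mode)
  stopifnot(A_plus >= 0, A_minus >= 0, tau_plus > 0, tau_minus > 0,
            A3_plus >= 0, tau_y > 0)
  structure(list(A_plus = A_plus, A_minus = A_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, mode = mode, A3_plus = A3_plus,
                 tau_y = tau_y),
            class = "stdp_params")
}

#' Is the rule in the BCM regime?
#'
#' TRUE iff `A_plus > A_minus` (potentiation dominates on the short time
#' scale) and `A_minus * tau_minus > A_plus * tau_plus` (overall weakening
#' dominates), the conditions under which [bcm_threshold()] is positive.
#'
#' @param p An [stdp_params()] object.
#' @export
is_bcm_regime <- function(p) {
  p$A_plus > p$A_minus && p$A_minus * p$tau_minus > p$A_plus * p$tau_plus
}

#' STDP pairing state
#'
#' Event-driven bookkeeping for one postsynaptic neuron with `n_syn`
#' afferents: last pre spike time per synapse, last post spike time, the
#' potentiation accumulator (nearest mode: sum of exponentially discounted
#' presynaptic spikes since the last postsynaptic spike), the pre/post traces
#' of the all-to-all mode, and the slow post trace of the triplet mode.
#' Simultaneous pre/post spikes (`dt = 0`) contribute nothing and pair with
#' the next partner spike instead.
#'
#' @param n_syn Number of afferent synapses.
#' @param p An [stdp_params()].
#' @return An object of class `pairing_state`.
#' @export
pairing_state <- function(n_syn, p = stdp_params()) {
  structure(list(
    params = p, n_syn = as.integer(n_syn),
    t_pre = rep(-Inf, n_syn), t_post = -Inf,
    # potentiation accumulator (value as of time `t_acc`), nearest/triplet mode
    ltp_acc = numeric(n_syn), t_acc = 0,
    # all-to-all traces
    x_pre = numeric(n_syn), y_post = 0,
    # triplet slow post trace
    y_slow = 0
  ), class = "pairing_state")
}

# decay the accumulators of a pairing_state to time t
decay_pairing <- function(s, t) {
  if (t > s$t_acc) {
    d <- t - s$t_acc
    s$ltp_acc <- s$ltp_acc * exp(-d / s$params$tau_plus)
    s$x_pre <- s$x_pre * exp(-d / s$params$tau_plus)
    s$y_post <- s$y_post * exp(-d / s$params$tau_minus)
    s$y_slow <- s$y_slow * exp(-d / s$params$tau_y)
    s$t_acc <- t
  }
  s
}

#' Process a presynaptic spike
#'
#' Applies the depression branch: pairing with the most recent postsynaptic
#' spike, \eqn{\Delta w = -A_- e^{-(t - \hat t_{post})/\tau_-}} (zero if the
#' neuron has not fired yet, or fired only simultaneously). In all-to-all
#' mode the depression reads the exponential post trace instead.
#'
#' @param s A [pairing_state()].
#' @param synapse_id Index of the spiking synapse.
#' @param t Spike time (ms); must not precede recorded times.
#' @return A list with `dw` (scalar weight change for that synapse) and the
#'   updated `state`.
#' @export
stdp_on_pre <- function(s, synapse_id, t) {
  p <- s$params
  if (t < s$t_post || t < s$t_pre[synapse_id])
    stop("spike times must be nondecreasing")
  s <- decay_pairing(s, t)
  dw <- if (p$mode == "all_to_all") {
    -p$A_minus * s$y_post
  } else if (is.finite(s$t_post) && t > s$t_post) {
    -p$A_minus * exp(-(t - s$t_post) / p$tau_minus)
  } else 0
  s$ltp_acc[synapse_id] <- s$ltp_acc[synapse_id] + 1
  s$x_pre[synapse_id] <- s$x_pre[synapse_id] + 1
  s$t_pre[synapse_id] <- t
  list(dw = dw, state = s)
}

#' Process a postsynaptic spike
#'
#' Applies the potentiation branch to every synapse. Nearest mode: each
#' presynaptic spike since the previous postsynaptic spike is paired with
#' this spike, \eqn{\Delta w_i = A_+ \sum_k e^{-(t - t_{pre,k})/\tau_+}}
#' (the discounted accumulator, which is then reset). All-to-all mode reads
#' the non-resetting pre traces. Triplet mode scales the nearest-mode
#' potentiation by \eqn{A_+ + A_3^+ \bar y_{slow}} with the slow post trace
#' taken just before this spike. Presynaptic spikes at exactly time `t`
#' contribute nothing (they pair with the next postsynaptic spike).
#'
#' @inheritParams stdp_on_pre
#' @param t Spike time (ms).
#' @return A list with `dw` (per-synapse weight changes) and the updated
#'   `state`.
#' @export
stdp_on_post <- function(s, t) {
  p <- s$params
  if (t < s$t_post || any(t < s$t_pre)) stop("spike times must be nondecreasing")
  s <- decay_pairing(s, t)
  # exclude simultaneous pre spikes from this pairing
  simult <- is.finite(s$t_pre) & s$t_pre == t
  amp <- if (p$mode == "triplet") p$A_plus + p$A3_plus * s$y_slow else p$A_plus
  dw <- if (p$mode == "all_to_all") {
    p$A_plus * (s$x_pre - as.numeric(simult))
  } else {
    amp * (s$ltp_acc - as.numeric(simult))
  }
  # reset the nearest-neighbor accumulator; simultaneous pres carry over
  s$ltp_acc <- as.numeric(simult)
  s$y_post <- s$y_post + 1
  s$y_slow <- s$y_slow + 1
  s$t_post <- t
  list(dw = dw, state = s)
}

#' Clip weights at zero
#'
#' Weights are sign-constrained: any weight driven negative by plasticity is
#' clipped to zero.
#'
#' @param w Numeric weight vector or matrix.
#' @return `pmax(w, 0)`, shape preserved.
#' @export
clip_nonnegative <- function(w) {
  w[] <- pmax(w, 0)
  w
}

#' Synaptic scaling configuration
#'
#' @param W_total Target norm of each scaled scope.
#' @param norm_order `"L1"` (sum of weights, the spiking default) or `"L2"`
#'   (Euclidean norm, used by the rate model).
#' @param scope `"all"` (one scope) or `"per_population"` (independent scopes
#'   given by masks, e.g. on/off input populations).
#' @param w_max Per-synapse saturation bound (the hard upper limit of
#'   additive STDP models); `Inf` disables it. With L1 scaling the bound is
#'   honored exactly: saturated weights are pinned at `w_max` and the
#'   remaining mass is distributed over the unsaturated weights
#'   (water-filling), so the scope still sums to `W_total`.
#' @return An object of class `scaling_config`.
#' @export
scaling_config <- function(W_total = 100, norm_order = c("L1", "L2"),
                           scope = c("all", "per_population"),
                           w_max = Inf) {
  norm_order <- match.arg(norm_order)
  scope <- match.arg(scope)
  stopifnot(W_total > 0, w_max > 0)
  if (is.finite(w_max) && norm_order == "L2")
    stop("w_max is only supported with L1 scaling")
  structure(list(W_total = W_total, norm_order = norm_order, scope = scope,
                 w_max = w_max),
            class = "scaling_config")
}

#' Multiplicative synaptic scaling
#'
#' Divides each scope's weights by `norm / W_total` so the scope's norm
#' equals `W_total` exactly — a homeostatic renormalization applied after
#' each sample presentation. A scope whose weights are all zero is a dead
#' scope and raises an error.
#'
#' @param w Nonnegative weight vector.
#' @param cfg A [scaling_config()].
#' @param population_masks Optional list of index/logical vectors, one per
#'   scope (required when `cfg$scope == "per_population"`).
#' @return The rescaled weight vector.
#' @export
scale_weights <- function(w, cfg, population_masks = NULL) {
  masks <- if (cfg$scope == "per_population") {
    if (is.null(population_masks)) stop("per_population scaling requires population_masks")
    population_masks
  } else list(seq_along(w))
  wmax <- cfg$w_max %||% Inf
  for (m in masks) {
    ws <- w[m]
    nrm <- if (cfg$norm_order == "L1") sum(ws) else sqrt(sum(ws^2))
    if (!is.finite(nrm) || nrm <= 0)
      stop("dead scope: all weights zero, cannot rescale")
    ws <- ws * (cfg$W_total / nrm)
    if (is.finite(wmax) && any(ws > wmax)) {
      # water-filling: pin saturated weights, rescale the rest to preserve
      # the scope total
      for (it in 1:length(ws)) {
        sat <- ws >= wmax
        if (!any(ws > wmax)) break
        ws[sat] <- wmax
        rem <- cfg$W_total - sum(sat) * wmax
        if (rem <= 0 || !any(!sat)) { ws[!sat] <- 0; break }
        free_sum <- sum(ws[!sat])
        if (free_sum <= 0) break
        ws[!sat] <- ws[!sat] * (rem / free_sum)
      }
    }
    w[m] <- ws
  }
  w
}

#' Expected nearest-neighbor STDP drift for independent Poisson trains
#'
#' For independent pre/post Poisson trains at rates \eqn{\rho_{pre}},
#' \eqn{\rho_{post}}, the waiting time from a presynaptic spike to its nearest
#' postsynaptic partner on either side is exponential, so each branch is an
#' elementary integral and
#' \deqn{\frac{dw}{dt} = \rho_{pre}\left[
#'   \frac{A_+\tau_+\rho_{post}}{1+\tau_+\rho_{post}} -
#'   \frac{A_-\tau_-\rho_{post}}{1+\tau_-\rho_{post}}\right]}
#' (time constants in seconds). The drift is proportional to the presynaptic
#' rate and changes sign in the postsynaptic rate at [bcm_threshold()] — the
#' BCM correspondence of this STDP scheme.
#'
#' @param rho_pre,rho_post Pre-/postsynaptic rates (Hz), vectorized.
#' @param p An [stdp_params()].
#' @return Expected drift in weight units per second.
#' @export
expected_drift_nn <- function(rho_pre, rho_post, p = stdp_params()) {
  stopifnot(all(rho_pre >= 0), all(rho_post >= 0))
  tp <- p$tau_plus / 1000
  tm <- p$tau_minus / 1000
  rho_pre * (p$A_plus * tp * rho_post / (1 + tp * rho_post) -
               p$A_minus * tm * rho_post / (1 + tm * rho_post))
}

#' Fixed BCM threshold of nearest-neighbor STDP
#'
#' The unique positive postsynaptic rate at which [expected_drift_nn()]
#' crosses zero:
#' \deqn{\theta = \frac{A_-\tau_- - A_+\tau_+}{\tau_+\tau_-(A_+ - A_-)}}
#' (time constants in seconds). Requires the BCM-regime conditions
#' `A_plus > A_minus` and `A_minus * tau_minus >= A_plus * tau_plus`; at
#' equality of the second the threshold is zero.
#'
#' @param p An [stdp_params()].
#' @return Threshold rate in Hz.
#' @export
bcm_threshold <- function(p = stdp_params()) {
  if (p$A_plus <= p$A_minus)
    stop("outside BCM regime: requires A_plus > A_minus (potentiation must dominate on the short time scale)")
  if (p$A_minus * p$tau_minus < p$A_plus * p$tau_plus)
    stop("outside BCM regime: requires A_minus*tau_minus >= A_plus*tau_plus (overall depression must dominate)")
  tp <- p$tau_plus / 1000
  tm <- p$tau_minus / 1000
  (p$A_minus * tm - p$A_plus * tp) / (tp * tm * (p$A_plus - p$A_minus))
}

#' Monte-Carlo STDP drift on independent Poisson trains
#'
#' Simulates independent Poisson pre/post spike trains and accumulates the
#' nearest-neighbor pairings directly (each pre spike paired with its nearest
#' preceding post for depression and nearest following post for potentiation),
#' returning the empirical drift and its standard error. This is the
#' simulation route against which the closed form [expected_drift_nn()] is
#' validated.
#'
#' @param rho_pre,rho_post Rates (Hz).
#' @param p An [stdp_params()].
#' @param duration Simulated time (s).
#' @param n_rep Independent repetitions (for the standard error).
#' @return A list with `drift` (weight units per second), `se`, and
#'   `duration`.
#' @export
stdp_drift_mc <- function(rho_pre, rho_post, p = stdp_params(),
                          duration = 1000, n_rep = 20) {
  drifts <- vapply(seq_len(n_rep), function(i) {
    pre <- sort(stats::runif(stats::rpois(1, rho_pre * duration), 0, duration))
    post <- sort(stats::runif(stats::rpois(1, rho_post * duration), 0, duration))
    if (!length(pre) || !length(post)) return(0)
    tp <- p$tau_plus / 1000
    tm <- p$tau_minus / 1000
    idx <- findInterval(pre, post)          # posts at or before each pre
    prev_ok <- idx >= 1
    ltd <- -p$A_minus * sum(exp(-(pre[prev_ok] - post[idx[prev_ok]]) / tm))
    nxt <- idx + 1
    next_ok <- nxt <= length(post)
    ltp <- p$A_plus * sum(exp(-(post[nxt[next_ok]] - pre[next_ok]) / tp))
    (ltp + ltd) / duration
  }, numeric(1))
  list(drift = mean(drifts), se = stats::sd(drifts) / sqrt(n_rep),
       duration = duration)
}
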