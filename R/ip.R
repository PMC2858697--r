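#' Intrinsic-plasticity configuration
#'
#' Stochastic gradient descent on the per-sample objective
#' [ip_sample_objective()], whose expectation equals (up to a constant) the
#' Kullback-Leibler divergence between the neuron's instantaneous-rate
#' distribution and an exponential with mean `mu_goal`.
#'
#' @param eta_ip Learning rate per update (dimensionless); `>= 0`.
#' @param mu_goal Target mean rate (Hz).
#' @param update_every Steps between updates (default: every step).
#' @return An object of class `ip_config`.
#' @export
ip_config <- function(eta_ip = 1e-4, mu_goal = 5, update_every = 1L) {
  stopifnot(eta_ip >= 0, mu_goal > 0, update_every >= 1)
  structure(list(eta_ip = eta_ip, mu_goal = mu_goal,
                 update_every = as.integer(update_every)),
            class = "ip_config")
}

#' Per-sample intrinsic-plasticity objective
#'
#' The stochastic (single-sample) objective
#' \eqn{F(u) = -\log g'(u) + g(u)/\mu}, whose expectation over the stationary
#' membrane-potential distribution differs from
#' \eqn{D_{KL}(p_g \,\|\, \mathrm{Exp}(\mu))} only by a parameter-independent
#' constant: the first term is the (negative) log-density Jacobian of the
#' transform \eqn{u \mapsto g(u)} (entropy maximization), the second penalizes
#' mean rate (the metabolic constraint).
#'
#' @param u Membrane potential (mV), vectorized.
#' @param p [gain_params()].
#' @param mu_goal Target mean rate (Hz).
#' @return Objective value(s), finite.
#' @export
ip_sample_objective <- function(u, p, mu_goal) {
  gr <- gain_gradients(u, p)
  if (any(gr$d_u <= 0) || any(!is.finite(gr$d_u)))
    stop("gain slope vanished numerically; objective undefined")
  -log(gr$d_u) + gr$g / mu_goal
}

#' Analytic gradient of the per-sample IP objective
#'
#' Closed-form partials of [ip_sample_objective()] in `(r0, u0, u_alpha)`.
#' With \eqn{x = (u-u_0)/u_\alpha}, \eqn{\sigma = \mathrm{logistic}(x)} and
#' \eqn{s = \mathrm{softplus}(x)}:
#' \deqn{\partial_{r_0} F = -1/r_0 + s/\mu}
#' \deqn{\partial_{u_0} F = (1-\sigma)/u_\alpha - r_0 \sigma / (u_\alpha \mu)}
#' \deqn{\partial_{u_\alpha} F = (1 + x(1-\sigma))/u_\alpha - r_0 \sigma x / (u_\alpha \mu)}
#'
#' @inheritParams ip_sample_objective
#' @return A list with `d_r0`, `d_u0`, `d_ualpha` (vectorized over `u`).
#' @export
ip_gradients <- function(u, p, mu_goal) {
  ua <- p$u_alpha
  x <- (u - p$u0) / ua
  sg <- logistic(x)
  s <- softplus(x)
  list(
    d_r0 = -1 / p$r0 + s / mu_goal,
    d_u0 = (1 - sg) / ua - p$r0 * sg / (ua * mu_goal),
    d_ualpha = (1 + x * (1 - sg)) / ua - p$r0 * sg * x / (ua * mu_goal)
  )
}

#' One intrinsic-plasticity update
#'
#' Moves each gain parameter one stochastic-gradient-descent step downhill on
#' [ip_sample_objective()]. Updates that would drive `r0` or `u_alpha` to or
#' below zero are clamped at a small positive floor (with a warning).
#'
#' @param p [gain_params()].
#' @param u Membrane potential sample (mV).
#' @param cfg An [ip_config()].
#' @param floors Positive floors for `r0` and `u_alpha` (named vector); by
#'   default `1e-6` times the current values.
#' @return The updated [gain_params()].
#' @export
ip_update <- function(p, u, cfg, floors = NULL) {
  if (cfg$eta_ip == 0) return(p)
  if (is.null(floors)) floors <- c(r0 = 1e-6 * p$r0, u_alpha = 1e-6 * p$u_alpha)
  g <- ip_gradients(u, p, cfg$mu_goal)
  r0 <- p$r0 - cfg$eta_ip * g$d_r0
  u0 <- p$u0 - cfg$eta_ip * g$d_u0
  ua <- p$u_alpha - cfg$eta_ip * g$d_ualpha
  if (r0 < floors[["r0"]]) {
    warning("IP update clamped r0 at its positive floor")
    r0 <- floors[["r0"]]
  }
  if (ua < floors[["u_alpha"]]) {
    warning("IP update clamped u_alpha at its positive floor")
    ua <- floors[["u_alpha"]]
  }
  gain_params(r0 = r0, u0 = u0, u_alpha = ua)
}

#' Configuration and state of the simplified mean-rate-only rule
#'
#' The control rule adjusts only the threshold `u0` so that a low-pass
#' estimate of the firing rate matches `r_goal`; the shape of the output
#' distribution is left unconstrained (it typically becomes narrow and
#' Gaussian rather than exponential).
#'
#' @param eta_mr Learning rate (mV per Hz of rate error, per update).
#' @param r_goal Target mean rate (Hz).
#' @param tau_r Time constant of the low-pass rate estimator (ms).
#' @param r_bar Initial rate estimate (Hz).
#' @return An object of class `mean_rate_ip_config`.
#' @export
mean_rate_ip_config <- function(eta_mr = 5e-5, r_goal = 5, tau_r = 1000,
                                r_bar = 0) {
  stopifnot(eta_mr > 0, r_goal > 0, tau_r > 0, r_bar >= 0)
  structure(list(eta_mr = eta_mr, r_goal = r_goal, tau_r = tau_r,
                 r_bar = r_bar),
            class = "mean_rate_ip_config")
}

#' Low-pass firing-rate estimator
#'
#' Exponential filter of the spike train,
#' \eqn{\bar r \leftarrow \bar r + (dt/\tau_r)(s \cdot 1000/dt - \bar r)}
#' with `s` the 0/1 spike indicator; unbiased for constant-rate Poisson input
#' in steady state.
#'
#' @param mr A [mean_rate_ip_config()].
#' @param spike Spike indicator (0 or 1).
#' @param dt Step size (ms).
#' @return The updated `mean_rate_ip_config` (field `r_bar`).
#' @export
lowpass_rate <- function(mr, spike, dt) {
  stopifnot(dt > 0)
  mr$r_bar <- mr$r_bar + (dt / mr$tau_r) * (spike * 1000 / dt - mr$r_bar)
  mr
}

#' One update of the simplified mean-rate rule
#'
#' \eqn{\Delta u_0 = \eta_{mr} (\bar r - r_{goal})}: the threshold rises
#' (excitability falls) when the neuron fires above target, and falls when
#' below. `r0` and `u_alpha` are frozen.
#'
#' @param p [gain_params()].
#' @param mr A [mean_rate_ip_config()].
#' @return The updated [gain_params()].
#' @export
ip_mean_rate_update <- function(p, mr) {
  gain_params(r0 = p$r0, u0 = p$u0 + mr$eta_mr * (mr$r_bar - mr$r_goal),
              u_alpha = p$u_alpha)
}

#' Calibrate the mean-rate rule's learning rate against full IP
#'
#' Runs both rules in closed loop on the same fixed Gaussian membrane-potential
#' drive and returns the `eta_mr` whose settling time (first time the running
#' rate estimate stays within 10% of target) matches the full IP rule's within
#' a factor of two, found by bisection on a log grid.
#'
#' @param p0 Initial [gain_params()].
#' @param ip An [ip_config()].
#' @param u_mean,u_sd Gaussian drive parameters (mV).
#' @param n_steps Steps per probe run.
#' @param dt Step size (ms).
#' @return Calibrated `eta_mr` (scalar).
#' @export
calibrate_eta_mr <- function(p0 = gain_params(), ip = ip_config(),
                             u_mean = -60, u_sd = 3, n_steps = 2e5, dt = 1) {
  settle_full <- ip_settling_time(p0, ip, u_mean, u_sd, n_steps, dt)
  candidates <- 10^seq(-6, -3, by = 0.5)
  settles <- vapply(candidates, function(eta) {
    mr_settling_time(p0, mean_rate_ip_config(eta_mr = eta, r_goal = ip$mu_goal),
                     u_mean, u_sd, n_steps, dt)
  }, numeric(1))
  ok <- which(is.finite(settles) & settles <= 2 * settle_full &
                settles >= settle_full / 2)
  if (!length(ok)) {
    # fall back to the closest settling time
    ok <- which.min(abs(log(pmax(settles, 1)) - log(settle_full)))
  }
  candidates[ok[1]]
}

#' Run the full IP rule in closed loop on a membrane-potential sequence
#'
#' Applies one [ip_update()] step per sample of `u` (with the per-step
#' arithmetic inlined for speed; a short run is verified against repeated
#' `ip_update()` calls in the test suite). Used to study the stationary
#' output-rate distribution that intrinsic plasticity produces on a fixed
#' drive.
#'
#' @param p0 Initial [gain_params()].
#' @param ip An [ip_config()].
#' @param u Membrane-potential samples (mV), one per update.
#' @param record_every Steps between trajectory records (0 = none).
#' @return A list with the final `params` and a `trajectory` data frame.
#' @export
run_ip_closed_loop <- function(p0, ip, u, record_every = 0) {
  r0 <- p0$r0; u0 <- p0$u0; ua <- p0$u_alpha
  mu <- ip$mu_goal; eta <- ip$eta_ip
  floor_r0 <- 1e-6 * p0$r0; floor_ua <- 1e-6 * p0$u_alpha
  n <- length(u)
  n_rec <- if (record_every > 0) n %/% record_every else 0
  traj <- matrix(NA_real_, n_rec, 4)
  rec <- 0L
  for (i in seq_len(n)) {
    z <- (u[i] - u0) / ua
    sg <- 1 / (1 + exp(-z))
    sp <- if (z > 35) z else log1p(exp(z))
    d_r0 <- -1 / r0 + sp / mu
    d_u0 <- (1 - sg) / ua - r0 * sg / (ua * mu)
    d_ua <- (1 + z * (1 - sg)) / ua - r0 * sg * z / (ua * mu)
    r0 <- r0 - eta * d_r0
    u0 <- u0 - eta * d_u0
    ua <- ua - eta * d_ua
    if (r0 < floor_r0) r0 <- floor_r0
    if (ua < floor_ua) ua <- floor_ua
    if (n_rec > 0 && i %% record_every == 0L) {
      rec <- rec + 1L
      traj[rec, ] <- c(i, r0, u0, ua)
    }
  }
  traj <- as.data.frame(traj)
  names(traj) <- c("step", "r0", "u0", "u_alpha")
  list(params = gain_params(r0, u0, ua), trajectory = traj)
}

# settling time (steps) of the full IP rule on Gaussian drive
ip_settling_time <- function(p, ip, u_mean, u_sd, n_steps, dt) {
  u <- stats::rnorm(n_steps, u_mean, u_sd)
  rbar <- 0
  a <- dt / 1000  # smoothing over ~1 s of model time
  last_out <- n_steps
  for (i in seq_len(n_steps)) {
    p <- ip_update(p, u[i], ip)
    rbar <- rbar + a * (gain(u[i], p) - rbar)
    if (abs(rbar - ip$mu_goal) > 0.1 * ip$mu_goal) last_out <- i
  }
  if (last_out >= n_steps) Inf else last_out
}

# settling time (steps) of the mean-rate rule on the same drive
mr_settling_time <- function(p, mr, u_mean, u_sd, n_steps, dt) {
  u <- stats::rnorm(n_steps, u_mean, u_sd)
  rbar <- 0
  a <- dt / 1000
  last_out <- n_steps
  for (i in seq_len(n_steps)) {
    g <- gain(u[i], p)
    spike <- as.numeric(stats::runif(1) < 1 - exp(-g * dt / 1000))
    mr <- lowpass_rate(mr, spike, dt)
    p <- ip_mean_rate_update(p, mr)
    rbar <- rbar + a * (g - rbar)
    if (abs(rbar - mr$r_goal) > 0.1 * mr$r_goal) last_out <- i
  }
  if (last_out >= n_steps) Inf else last_out
}
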