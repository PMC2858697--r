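#' Rate-model configuration
#'
#' The rate-based reference neuron: the same gain function as the spiking
#' model, driven by `u = u_rest + drive_scale * (w . x)`, with classic
#' Hebbian weight updates and an intrinsic-plasticity update per step.
#' With `norm_order = "L1"` the weights are kept positive with constant sum
#' (which confines the weight vector to the first quadrant); `"L2"` keeps
#' the Euclidean norm constant and allows negative weights, removing that
#' limitation.
#'
#' @param eta_hebb Hebbian learning rate (per step).
#' @param eta_ip IP learning rate (per step).
#' @param norm_order `"L2"` (default) or `"L1"`.
#' @param W_total Target weight norm.
#' @param drive_scale mV of membrane drive per unit of `w . x`.
#' @param u_rest Resting potential (mV).
#' @param n_steps Steps per run.
#' @param mu_goal IP target rate (Hz).
#' @return An object of class `rate_model_config`.
#' @export
rate_model_config <- function(eta_hebb = 1e-4, eta_ip = 1e-3,
                              norm_order = c("L2", "L1"), W_total = 1,
                              drive_scale = 10, u_rest = -70,
                              n_steps = 2e5, mu_goal = 5) {
  norm_order <- match.arg(norm_order)
  stopifnot(eta_hebb >= 0, eta_ip >= 0, W_total > 0, drive_scale > 0)
  structure(list(eta_hebb = eta_hebb, eta_ip = eta_ip,
                 norm_order = norm_order, W_total = W_total,
                 drive_scale = drive_scale, u_rest = u_rest,
                 n_steps = as.integer(n_steps), mu_goal = mu_goal),
            class = "rate_model_config")
}

#' Rate response of the reference neuron
#'
#' `g(u_rest + drive_scale * (w . x))` using the shared gain function
#' [gain()].
#'
#' @param x Input vector.
#' @param w Weight vector (normalized per the run's configuration).
#' @param p [gain_params()].
#' @param cfg A [rate_model_config()].
#' @return Firing rate (Hz).
#' @export
rate_response <- function(x, w, p, cfg = rate_model_config()) {
  gain(cfg$u_rest + cfg$drive_scale * sum(w * x), p)
}

#' One Hebbian weight update with renormalization
#'
#' `w <- w + eta_hebb * nu * x`, followed by clipping at zero (L1 mode only)
#' and renormalization to the configured norm.
#'
#' @param w Weight vector.
#' @param x Input vector.
#' @param nu Output rate (Hz).
#' @param cfg A [rate_model_config()].
#' @return The updated, renormalized weight vector.
#' @export
hebb_step <- function(w, x, nu, cfg = rate_model_config()) {
  w <- w + cfg$eta_hebb * nu * x
  if (cfg$norm_order == "L1") {
    w <- pmax(w, 0)
    nrm <- sum(w)
  } else {
    nrm <- sqrt(sum(w^2))
  }
  if (nrm <= 0) stop("weight vector collapsed to zero norm")
  w * (cfg$W_total / nrm)
}

#' Run the rate-based demixing experiment
#'
#' At each step a fresh Laplacian source pair is drawn, mixed by the rotation
#' matrix at angle `theta`, passed through the gain function, and used for an
#' IP update (every step) and a Hebbian weight update. Under the sparse
#' output distribution enforced by IP, the weight vector rotates towards one
#' of the independent source directions.
#'
#' @param theta Mixing angle (radians).
#' @param cfg A [rate_model_config()].
#' @param p0 Initial [gain_params()].
#' @param w0 Initial weight vector (default: random direction).
#' @param record_every Steps between trajectory records.
#' @param source_sampler Function `n -> n x 2` source matrix (defaults to
#'   [sample_laplace_pair()]; replace to study other source distributions,
#'   e.g. one Laplacian and one Gaussian axis).
#' @return A list with final `w`, `params`, a trajectory data frame
#'   (`step`, `w1`, `w2`, `angle`, `r0`, `u0`, `u_alpha`, `nu_kurtosis` —
#'   the excess kurtosis of the rates in each recording window) and the last
#'   recorded output-rate samples `nu_samples`.
#' @export
run_rate_demixing <- function(theta, cfg = rate_model_config(),
                              p0 = gain_params(), w0 = NULL,
                              record_every = 1000,
                              source_sampler = sample_laplace_pair) {
  if (is.null(w0)) {
    a <- stats::runif(1, 0, 2 * pi)
    w0 <- c(cos(a), sin(a))
  }
  w <- w0 / sqrt(sum(w0^2)) * cfg$W_total
  if (cfg$norm_order == "L1") w <- pmax(abs(w), 1e-3)
  r0 <- p0$r0; u0 <- p0$u0; ua <- p0$u_alpha
  mu <- cfg$mu_goal
  eta_ip <- cfg$eta_ip; eta_h <- cfg$eta_hebb
  floor_r0 <- 1e-6 * p0$r0; floor_ua <- 1e-6 * p0$u_alpha
  l1 <- cfg$norm_order == "L1"
  s <- source_sampler(cfg$n_steps)
  x <- mix_rotate(s, theta)
  n_rec <- cfg$n_steps %/% record_every
  traj <- matrix(NA_real_, n_rec, 8)
  nu_buf <- numeric(record_every)
  nu_last <- numeric(0)
  rec <- 0L
  w1 <- w[1]; w2 <- w[2]
  for (i in seq_len(cfg$n_steps)) {
    x1 <- x[i, 1]; x2 <- x[i, 2]
    u <- cfg$u_rest + cfg$drive_scale * (w1 * x1 + w2 * x2)
    # intrinsic plasticity (inlined gradient step of the per-sample objective)
    z <- (u - u0) / ua
    sg <- 1 / (1 + exp(-z))
    sp <- if (z > 35) z else log1p(exp(z))
    d_r0 <- -1 / r0 + sp / mu
    d_u0 <- (1 - sg) / ua - r0 * sg / (ua * mu)
    d_ua <- (1 + z * (1 - sg)) / ua - r0 * sg * z / (ua * mu)
    r0 <- r0 - eta_ip * d_r0
    u0 <- u0 - eta_ip * d_u0
    ua <- ua - eta_ip * d_ua
    if (r0 < floor_r0) r0 <- floor_r0
    if (ua < floor_ua) ua <- floor_ua
    nu <- r0 * sp
    nu_buf[((i - 1L) %% record_every) + 1L] <- nu
    # Hebbian update with renormalization
    w1 <- w1 + eta_h * nu * x1
    w2 <- w2 + eta_h * nu * x2
    if (l1) {
      if (w1 < 0) w1 <- 0
      if (w2 < 0) w2 <- 0
      nrm <- w1 + w2
    } else {
      nrm <- sqrt(w1 * w1 + w2 * w2)
    }
    if (nrm <= 0) stop("weight vector collapsed to zero norm")
    k <- cfg$W_total / nrm
    w1 <- w1 * k; w2 <- w2 * k
    if (i %% record_every == 0L) {
      rec <- rec + 1L
      mnu <- mean(nu_buf)
      knu <- if (stats::sd(nu_buf) > 0)
        mean((nu_buf - mnu)^4) / stats::sd(nu_buf)^4 - 3 else NA_real_
      traj[rec, ] <- c(i, w1, w2,
                       estimate_angle(c(w1, w2), modulus = pi / 2),
                       r0, u0, ua, knu)
      nu_last <- nu_buf
    }
  }
  traj <- as.data.frame(traj)
  names(traj) <- c("step", "w1", "w2", "angle", "r0", "u0", "u_alpha",
                   "nu_kurtosis")
  list(w = c(w1, w2), params = gain_params(r0, u0, ua),
       trajectory = traj, nu_samples = nu_last, theta = theta)
}
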