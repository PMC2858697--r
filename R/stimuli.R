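#' Draw a pair of independent unit-variance Laplacian sources
#'
#' Each component is i.i.d. Laplace(0, b) with scale \eqn{b = 1/\sqrt 2}, so
#' the variance is 1 and the excess kurtosis is 3 — the supergaussian sources
#' of the demixing problem.
#'
#' @param n Number of pairs.
#' @return An `n x 2` matrix of source samples.
#' @export
sample_laplace_pair <- function(n = 1) {
  b <- 1 / sqrt(2)
  m <- matrix(stats::runif(2 * n) - 0.5, n, 2)
  -b * sign(m) * log1p(-2 * abs(m))
}

#' Mix two sources with a rotation matrix
#'
#' \eqn{x = R(\theta) s} with
#' \eqn{R = [[\cos\theta, -\sin\theta], [\sin\theta, \cos\theta]]}; the norm
#' of each sample is preserved.
#'
#' @param s Source vector of length 2, or an `n x 2` matrix.
#' @param theta Rotation angle (radians).
#' @return Mixed input(s) with the same shape as `s`.
#' @export
mix_rotate <- function(s, theta) {
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  if (is.matrix(s)) s %*% t(rot) else as.numeric(rot %*% s)
}

#' Split a signed 2-D input into on/off channels
#'
#' Nonnegative rectified encoding `(on1, off1, on2, off2)` with
#' `on_i = max(x_i, 0)`, `off_i = max(-x_i, 0)`; at most one of each pair is
#' nonzero and `on - off` reconstructs `x` exactly.
#'
#' @param x Numeric vector of length 2, or an `n x 2` matrix.
#' @return A length-4 vector (or `n x 4` matrix).
#' @export
onoff_encode <- function(x) {
  if (is.matrix(x)) {
    cbind(pmax(x[, 1], 0), pmax(-x[, 1], 0), pmax(x[, 2], 0), pmax(-x[, 2], 0))
  } else {
    c(pmax(x[1], 0), pmax(-x[1], 0), pmax(x[2], 0), pmax(-x[2], 0))
  }
}

#' Demixing task configuration
#'
#' @param theta Rotation angle (radians), in `[0, pi/2)`.
#' @param synapses_per_channel Independent synapses per on/off channel.
#' @param rate_scale Hz per unit channel amplitude (the on/off rates are
#'   scaled up to speed learning).
#' @param sample_duration Presentation time per sample (ms).
#' @return An object of class `demix_config`.
#' @export
demix_config <- function(theta = 0.5236, synapses_per_channel = 25,
                         rate_scale = 20, sample_duration = 200) {
  stopifnot(theta >= 0, theta < pi / 2, synapses_per_channel >= 1,
            rate_scale > 0, sample_duration > 0)
  structure(list(theta = theta,
                 synapses_per_channel = as.integer(synapses_per_channel),
                 rate_scale = rate_scale, sample_duration = sample_duration),
            class = "demix_config")
}

#' Generate independent Poisson spike trains
#'
#' One Bernoulli indicator per time bin per synapse with probability
#' `rate * dt / 1000`; each channel is replicated over `n_per_channel`
#' synapses with independent spikes at the same rate.
#'
#' @param rates Per-channel rates (Hz).
#' @param duration Train duration (ms).
#' @param dt Bin width (ms).
#' @param n_per_channel Synapses per channel.
#' @return A binary matrix with `duration/dt` rows (time bins) and
#'   `length(rates) * n_per_channel` columns (synapses, channel-major).
#' @export
poisson_trains <- function(rates, duration, dt = 1, n_per_channel = 1) {
  stopifnot(all(rates >= 0), duration > 0, dt > 0)
  prob <- rep(rates, each = n_per_channel) * dt / 1000
  if (any(prob > 1)) stop("rate * dt exceeds one spike per bin")
  n_steps <- round(duration / dt)
  n_syn <- length(prob)
  matrix(stats::runif(n_steps * n_syn) < rep(prob, each = n_steps),
         n_steps, n_syn) * 1L
}

#' Bars task configuration
#'
#' Foldiak's bars: samples are binary-OR superpositions of horizontal and
#' vertical bars of width `bar_width` at non-overlapping offsets on a
#' `grid x grid` image, so the basis has `2 * grid / bar_width` elements.
#' Bars appear independently with probability `p`
#' (`mode = "independent_p"`) or exactly `k` distinct bars are drawn
#' uniformly per sample (`mode = "exactly_k"`).
#'
#' @param grid Side length in pixels.
#' @param bar_width Bar width in pixels (1 or 2; grid must be even for 2).
#' @param mode `"independent_p"` or `"exactly_k"`.
#' @param p Per-bar appearance probability (independent mode).
#' @param k Bars per sample (exactly_k mode).
#' @param nu_bg Background pixel rate (Hz).
#' @param nu_max Rate of a bar pixel in a single-bar sample (Hz).
#' @param sample_duration Presentation time per sample (ms).
#' @return An object of class `bars_config`.
#' @export
bars_config <- function(grid = 5, bar_width = 1,
                        mode = c("independent_p", "exactly_k"),
                        p = 0.1, k = 4, nu_bg = 2, nu_max = 80,
                        sample_duration = 200) {
  mode <- match.arg(mode)
  stopifnot(bar_width %in% c(1, 2), grid >= 2, p >= 0, p <= 1,
            nu_bg >= 0, nu_max > nu_bg, sample_duration > 0)
  if (bar_width == 2 && grid %% 2 != 0) stop("grid must be even for 2-px bars")
  n_bars <- 2 * grid / bar_width
  if (mode == "exactly_k" && (k < 1 || k > n_bars))
    stop("k must be between 1 and the number of bars")
  structure(list(grid = as.integer(grid), bar_width = as.integer(bar_width),
                 mode = mode, p = p, k = as.integer(k), nu_bg = nu_bg,
                 nu_max = nu_max, sample_duration = sample_duration,
                 n_bars = as.integer(n_bars)),
            class = "bars_config")
}

#' Bar basis templates
#'
#' @param cfg A [bars_config()].
#' @return A list of binary `grid x grid` matrices: first the horizontal
#'   bars (top to bottom), then the vertical bars (left to right).
#' @export
bar_templates <- function(cfg) {
  g <- cfg$grid; wb <- cfg$bar_width
  offs <- seq(1, g, by = wb)
  horiz <- lapply(offs, function(r) {
    m <- matrix(0L, g, g); m[r:(r + wb - 1), ] <- 1L; m
  })
  vert <- lapply(offs, function(cc) {
    m <- matrix(0L, g, g); m[, cc:(cc + wb - 1)] <- 1L; m
  })
  c(horiz, vert)
}

#' Draw one bars sample
#'
#' @param cfg A [bars_config()].
#' @return A list with `grid` (binary matrix, pixelwise OR of the selected
#'   bar templates) and `bars` (integer ids of active bars).
#' @export
bars_sample <- function(cfg) {
  tmpl <- bar_templates(cfg)
  ids <- if (cfg$mode == "independent_p") {
    which(stats::runif(cfg$n_bars) < cfg$p)
  } else {
    sample.int(cfg$n_bars, cfg$k)
  }
  g <- matrix(0L, cfg$grid, cfg$grid)
  for (i in ids) g <- g | tmpl[[i]]
  list(grid = g * 1L, bars = ids)
}

#' Convert a bars image to per-pixel firing rates
#'
#' The binary image is L2-normalized and rescaled so that the bar pixels of a
#' single-bar sample map exactly to `nu_max`; each pixel's rate is then
#' `nu_bg + scaled * (nu_max - nu_bg)`. An empty image yields the background
#' rate everywhere. The normalization makes a bar in a one-bar sample
#' stronger than the same bar in a crowded sample.
#'
#' @param grid Binary image matrix.
#' @param cfg A [bars_config()].
#' @return A numeric matrix of rates (Hz), same shape as `grid`.
#' @export
bars_to_rates <- function(grid, cfg) {
  nrm <- sqrt(sum(grid^2))
  scaled <- if (nrm > 0) {
    grid / nrm * sqrt(cfg$grid * cfg$bar_width)
  } else grid * 0
  cfg$nu_bg + scaled * (cfg$nu_max - cfg$nu_bg)
}

#' Solve the dichotomous-Gaussian parameters for a target correlation
#'
#' To generate binary trains with per-bin spike probability
#' \eqn{p = \nu\, dt/1000} and pairwise indicator correlation `c`, latent
#' standard Gaussians are thresholded at \eqn{\gamma = \Phi^{-1}(1-p)}; the
#' latent correlation \eqn{\lambda} solves
#' \eqn{\Phi_2(-\gamma,-\gamma;\lambda) - p^2 = c\,p(1-p)}, found by bracketed
#' root-finding on the bivariate-normal orthant probability (computed by
#' one-dimensional quadrature).
#'
#' @param nu Mean rate (Hz).
#' @param c Target pairwise correlation of spike indicators, in `[0, 1)`.
#' @param dt Bin width (ms).
#' @return A list with `gamma`, `lam`, `p_bin` and the solver `residual`.
#' @export
solve_dichotomous_gaussian <- function(nu, c, dt = 1) {
  p <- nu * dt / 1000
  stopifnot(p > 0, p < 1, c >= 0, c < 1)
  gamma <- stats::qnorm(1 - p)
  if (c == 0) return(list(gamma = gamma, lam = 0, p_bin = p, residual = 0))
  target <- c * p * (1 - p) + p^2
  f <- function(lam) orthant_prob(gamma, lam) - target
  # orthant probability is increasing in lambda; bracket on [0, 1)
  sol <- stats::uniroot(f, c(0, 1 - 1e-9), tol = 1e-12)
  if (abs(sol$f.root) > 1e-8)
    stop("no latent correlation reproduces c at this rate/bin width")
  list(gamma = gamma, lam = sol$root, p_bin = p, residual = sol$f.root)
}

# P(Z1 > gamma, Z2 > gamma) for standard bivariate normal with correlation lam
orthant_prob <- function(gamma, lam) {
  if (lam == 0) return(stats::pnorm(-gamma)^2)
  if (lam >= 1) return(stats::pnorm(-gamma))
  integrand <- function(z)
    stats::dnorm(z) * stats::pnorm((lam * z - gamma) / sqrt(1 - lam^2))
  stats::integrate(integrand, gamma, Inf, rel.tol = 1e-11,
                   abs.tol = 1e-14)$value
}

#' Correlation specification for spike-train generation
#'
#' All channels share the same mean rate `nu`; the channels inside each
#' member set are pairwise correlated with coefficient `c`
#' (equicorrelated), channels across sets and background channels are
#' uncorrelated. The latent threshold and correlation are derived with
#' [solve_dichotomous_gaussian()].
#'
#' @param nu Common mean rate (Hz).
#' @param c Target pairwise correlation in `[0, 1)`.
#' @param member_sets List of disjoint integer vectors (channel indices).
#' @param n_channels Total number of channels.
#' @param dt Bin width (ms).
#' @return An object of class `correlation_spec`.
#' @export
correlation_spec <- function(nu, c, member_sets, n_channels, dt = 1) {
  all_members <- unlist(member_sets)
  if (anyDuplicated(all_members)) stop("member sets must be disjoint")
  if (length(all_members) && max(all_members) > n_channels)
    stop("member index exceeds n_channels")
  sol <- solve_dichotomous_gaussian(nu, c, dt)
  structure(list(nu = nu, c = c, member_sets = member_sets,
                 n_channels = as.integer(n_channels), dt = dt,
                 gamma = sol$gamma, lam = sol$lam),
            class = "correlation_spec")
}

#' Generate correlated Poisson-like spike trains
#'
#' Per bin, each member set shares a latent common factor:
#' \eqn{z_i = \sqrt\lambda z_{set} + \sqrt{1-\lambda}\,\epsilon_i} (valid for
#' an equicorrelated set), background channels use independent latents; a
#' channel spikes when its latent exceeds \eqn{\gamma}. Every channel's mean
#' rate is `nu` regardless of membership.
#'
#' @param spec A [correlation_spec()].
#' @param duration Train duration (ms).
#' @return Binary matrix, `duration/dt` rows by `n_channels` columns.
#' @export
correlated_trains <- function(spec, duration) {
  n_steps <- round(duration / spec$dt)
  z <- matrix(stats::rnorm(n_steps * spec$n_channels), n_steps,
              spec$n_channels)
  if (spec$lam > 0) {
    sl <- sqrt(spec$lam); se <- sqrt(1 - spec$lam)
    for (m in spec$member_sets) {
      zc <- stats::rnorm(n_steps)
      z[, m] <- sl * zc + se * z[, m]
    }
  }
  (z > spec$gamma) * 1L
}

#' Convert a binary spike matrix to a two-column raster table
#'
#' @param spikes Binary matrix, time bins x channels.
#' @param dt Bin width (ms).
#' @return A data frame with `channel_id` and `spike_time_ms` (bin centers),
#'   suitable for plain-text raster export.
#' @export
raster_to_df <- function(spikes, dt = 1) {
  idx <- which(spikes == 1L, arr.ind = TRUE)
  df <- data.frame(channel_id = idx[, 2],
                   spike_time_ms = (idx[, 1] - 0.5) * dt)
  df[order(df$channel_id, df$spike_time_ms), , drop = FALSE]
}

#' Synthetic grayscale test image
#'
#' A sum of oriented gratings plus white noise — a stand-in raster so the
#' image-preprocessing path runs without external data.
#'
#' @param size Side length (pixels).
#' @param n_gratings Number of oriented gratings.
#' @return A numeric `size x size` intensity matrix.
#' @export
synthetic_test_image <- function(size = 128, n_gratings = 4) {
  xy <- expand.grid(x = seq_len(size), y = seq_len(size))
  img <- matrix(0, size, size)
  for (i in seq_len(n_gratings)) {
    ang <- pi * (i - 1) / n_gratings
    freq <- 2 * pi * (0.03 + 0.03 * i)
    img <- img + matrix(sin(freq * (cos(ang) * xy$x + sin(ang) * xy$y) +
                              i), size, size)
  }
  img + matrix(stats::rnorm(size^2, sd = 0.2), size, size)
}

#' Preprocess an intensity image into on/off rate maps
#'
#' Difference-of-Gaussians filtering (removing the DC component), random
#' patch extraction, rejection of low-contrast patches, per-patch
#' z-scoring, rectification into on and off maps, and linear mapping of the
#' rectified values to firing rates in `[nu_bg, nu_max]`.
#'
#' @param image 2-D intensity matrix.
#' @param n_patches Patches to extract.
#' @param dog_center,dog_surround Gaussian widths of the filter (pixels).
#' @param patch_size Patch side length (pixels).
#' @param contrast_floor Minimum patch standard deviation (pre-z-scoring).
#' @param nu_bg,nu_max Rate range (Hz).
#' @return A list of patches, each with matrices `on` and `off` (rates, Hz).
#' @export
preprocess_image_patches <- function(image, n_patches = 10, dog_center = 1,
                                     dog_surround = 3, patch_size = 10,
                                     contrast_floor = 0.1, nu_bg = 2,
                                     nu_max = 40) {
  stopifnot(nrow(image) > patch_size, ncol(image) > patch_size)
  filt <- dog_filter_image(image, dog_center, dog_surround)
  out <- list()
  tries <- 0
  while (length(out) < n_patches && tries < 50 * n_patches) {
    tries <- tries + 1
    r <- sample.int(nrow(filt) - patch_size + 1, 1)
    cc <- sample.int(ncol(filt) - patch_size + 1, 1)
    patch <- filt[r:(r + patch_size - 1), cc:(cc + patch_size - 1)]
    if (stats::sd(patch) < contrast_floor) next
    patch <- (patch - mean(patch)) / stats::sd(patch)
    # scale rectified values into [0, 1] by the patch maximum magnitude
    scale <- max(abs(patch))
    out[[length(out) + 1]] <- list(
      on = nu_bg + pmax(patch, 0) / scale * (nu_max - nu_bg),
      off = nu_bg + pmax(-patch, 0) / scale * (nu_max - nu_bg))
  }
  if (!length(out)) stop("no patch passed the contrast floor")
  out
}

# separable Gaussian blur, then center - surround
dog_filter_image <- function(image, s_center, s_surround) {
  gauss_blur(image, s_center) - gauss_blur(image, s_surround)
}

gauss_blur <- function(image, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  # reflect-pad and convolve rows then columns
  conv_1d <- function(m) {
    n <- nrow(m)
    idx <- c(rev(seq_len(half)), seq_len(n), n + 1 - rev(seq_len(half)))
    padded <- m[pmin(pmax(idx, 1), n), , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * padded[j:(j + n - 1), , drop = FALSE]
    out
  }
  t(conv_1d(t(conv_1d(image))))
}
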