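#' Project learned on/off channel weights back to the 2-D input space
#'
#' The four summed channel weights `(W1_on, W1_off, W2_on, W2_off)` are
#' mapped to a 2-D vector by the minimum-error projection onto the rectified
#' on/off encoding subspace: per dimension the dominant channel wins,
#' `v_i = W_on,i` if `W_on,i >= W_off,i` (sign +, ties toward +) and
#' `v_i = -W_off,i` otherwise — the exact minimizer of
#' \eqn{\|w - \mathrm{enc}(v)\|^2} where \eqn{\mathrm{enc}} places the
#' positive part of `v` on the on channel and the negative part on the off
#' channel.
#'
#' @param w Length-4 nonnegative vector of summed channel weights, ordered
#'   `(on1, off1, on2, off2)`.
#' @return A 2-D vector (signed receptive-field direction).
#' @export
project_demix_weights <- function(w) {
  stopifnot(length(w) == 4)
  if (any(w < 0)) stop("channel sums must be nonnegative")
  if (all(w == 0)) stop("all-zero channel weights cannot be projected")
  v1 <- if (w[1] >= w[2]) w[1] else -w[2]
  v2 <- if (w[3] >= w[4]) w[3] else -w[4]
  c(v1, v2)
}

#' Angle of a 2-D vector folded modulo pi or pi/2
#'
#' @param v Nonzero 2-D vector.
#' @param modulus Fold the angle into `[0, modulus)`; `pi` identifies
#'   opposite directions, `pi/2` additionally identifies orthogonal axes
#'   (useful for comparing against a source axis pair).
#' @return Angle in radians, in `[0, modulus)`.
#' @export
estimate_angle <- function(v, modulus = pi / 2) {
  if (sqrt(sum(v^2)) == 0) stop("cannot estimate the angle of a zero vector")
  a <- atan2(v[2], v[1]) %% modulus
  if (a >= modulus) a - modulus else a
}

#' Receptive field as the on/off weight difference
#'
#' @param w_on,w_off Equal-shape weight maps of the on and off populations.
#' @return The signed map `w_on - w_off`.
#' @export
rf_from_onoff <- function(w_on, w_off) {
  if (!all(dim(as.matrix(w_on)) == dim(as.matrix(w_off))))
    stop("on and off maps must have the same shape")
  w_on - w_off
}

#' Count the bars present in a receptive field
#'
#' Operationalizes "the neuron learned exactly one bar": the field is
#' binarized at `frac` times its maximum; a bar is matched iff all of its
#' pixels are above threshold; the above-threshold set must equal the union
#' of matched bars up to a stray-pixel budget of `floor(n_pixels / 10)`.
#' Degenerate fields — all zero, or so flat that the threshold excludes no
#' pixel — contain no bar-like structure and count as 0, as does a field
#' whose stray pixels exceed the budget. Deterministic, and covariant under
#' the grid's bar-relabeling symmetries.
#'
#' @param rf Weight map (matrix matching the task geometry). Magnitudes are
#'   used, so a signed on/off difference map works too.
#' @param cfg The task's [bars_config()].
#' @param frac Threshold fraction of the maximum (default 0.5).
#' @return A list with `count` and `bars` (matched template ids).
#' @export
count_bars <- function(rf, cfg, frac = 0.5) {
  rf <- abs(rf)
  mx <- max(rf)
  if (mx <= 0) return(list(count = 0L, bars = integer(0)))
  above <- rf >= frac * mx
  if (all(above)) return(list(count = 0L, bars = integer(0)))
  tmpl <- bar_templates(cfg)
  matched <- which(vapply(tmpl, function(tm) all(above[tm == 1L]), logical(1)))
  if (!length(matched)) return(list(count = 0L, bars = integer(0)))
  covered <- Reduce(`|`, lapply(tmpl[matched], function(tm) tm == 1L))
  strays <- sum(above & !covered)
  if (strays > floor(length(rf) / 10)) return(list(count = 0L, bars = integer(0)))
  list(count = length(matched), bars = matched)
}

#' Summary statistics of an instantaneous-rate sample
#'
#' Mean, coefficient of variation, excess kurtosis, and the KL divergence of
#' the empirical distribution from an exponential with mean `mu_goal`
#' (histogram estimator over 50 equal-probability bins of the target). An
#' exponential output has CV 1, excess kurtosis 6 and KL near 0.
#'
#' @param g_samples Instantaneous rates (Hz); at least 1000 for a usable KL.
#' @param mu_goal Target mean (Hz).
#' @param n_bins Histogram bins for the KL estimator.
#' @return A list with `mean`, `cv`, `excess_kurtosis`, `kl` (nats; `NA`
#'   with a warning for a constant sequence).
#' @export
output_stats <- function(g_samples, mu_goal, n_bins = 50) {
  m <- mean(g_samples)
  s <- stats::sd(g_samples)
  if (!is.finite(s) || s == 0) {
    warning("constant rate sequence: KL and kurtosis undefined")
    return(list(mean = m, cv = 0, excess_kurtosis = NA_real_, kl = NA_real_))
  }
  kurt <- mean((g_samples - m)^4) / s^4 - 3
  edges <- stats::qexp(seq(0, 1, length.out = n_bins + 1), rate = 1 / mu_goal)
  edges[1] <- -Inf
  edges[n_bins + 1] <- Inf
  counts <- tabulate(findInterval(g_samples, edges,
                                  rightmost.closed = TRUE), n_bins)
  ph <- counts / length(g_samples)
  kl <- sum(ifelse(ph > 0, ph * log(ph * n_bins), 0))
  list(mean = m, cv = s / m, excess_kurtosis = kurt, kl = kl)
}

#' Pairwise decorrelation metrics of a neuron population
#'
#' Splits the per-sample mean rates into consecutive windows and computes,
#' per window, the mean over neuron pairs of the absolute Pearson
#' correlation and of the normalized mutual information
#' `I(X;Y) / min(H(X), H(Y))` estimated from joint histograms with
#' `n_bins` equal-width bins per neuron. Pairs containing a zero-variance
#' neuron in a window are skipped.
#'
#' @param rates Matrix, neurons x samples.
#' @param window Samples per window (must be at least 100).
#' @param n_bins Bins for the MI histogram.
#' @return A data frame with one row per window: `window`, `mean_abs_r`,
#'   `mean_nmi`, `n_pairs`.
#' @export
decorrelation_metrics <- function(rates, window, n_bins = 10) {
  stopifnot(nrow(rates) >= 2, window >= 100)
  n_win <- ncol(rates) %/% window
  out <- data.frame(window = seq_len(n_win), mean_abs_r = NA_real_,
                    mean_nmi = NA_real_, n_pairs = 0L)
  for (wi in seq_len(n_win)) {
    block <- rates[, ((wi - 1) * window + 1):(wi * window), drop = FALSE]
    keep <- which(apply(block, 1, stats::sd) > 0)
    if (length(keep) < 2) next
    rs <- c(); nmis <- c()
    for (i in keep[-length(keep)]) for (j in keep[keep > i]) {
      rs <- c(rs, abs(stats::cor(block[i, ], block[j, ])))
      nmis <- c(nmis, normalized_mi(block[i, ], block[j, ], n_bins))
    }
    out$mean_abs_r[wi] <- mean(rs)
    out$mean_nmi[wi] <- mean(nmis)
    out$n_pairs[wi] <- length(rs)
  }
  out
}

#' Normalized mutual information of two rate sequences
#'
#' `I(X;Y) / min(H(X), H(Y))` from a joint histogram over `n_bins`
#' equal-width bins per variable (natural log); lies in `[0, 1]` and equals
#' 1 for any deterministic one-to-one relation.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_bins Number of equal-width bins per variable.
#' @return NMI in `[0, 1]`.
#' @export
normalized_mi <- function(x, y, n_bins = 10) {
  bx <- discretize_equal_width(x, n_bins)
  by <- discretize_equal_width(y, n_bins)
  joint <- table(factor(bx, levels = seq_len(n_bins)),
                 factor(by, levels = seq_len(n_bins)))
  pj <- joint / sum(joint)
  px <- rowSums(pj); py <- colSums(pj)
  hx <- -sum(ifelse(px > 0, px * log(px), 0))
  hy <- -sum(ifelse(py > 0, py * log(py), 0))
  if (hx == 0 || hy == 0) return(0)
  outer_p <- outer(px, py)
  mi <- sum(ifelse(pj > 0, pj * log(pj / outer_p), 0))
  min(1, max(0, mi / min(hx, hy)))
}

discretize_equal_width <- function(x, n_bins) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(1L, length(x)))
  b <- findInterval(x, seq(rng[1], rng[2], length.out = n_bins + 1),
                    rightmost.closed = TRUE)
  pmin(pmax(b, 1L), n_bins)
}

#' Spike-triggered average receptive field
#'
#' For zero-mean white stimuli, the mean-subtracted average of the stimulus
#' vectors over samples that elicited spikes estimates the linear receptive
#' field (reverse correlation).
#'
#' @param stimuli Matrix, samples x channels (zero-mean white across
#'   channels).
#' @param spikes Per-sample spike counts (length `nrow(stimuli)`).
#' @return The spike-triggered average vector.
#' @export
reverse_correlation <- function(stimuli, spikes) {
  if (sum(spikes) < 1) stop("no spikes: cannot reverse-correlate")
  if (all(apply(stimuli, 2, stats::sd) == 0))
    stop("constant stimulus: cannot reverse-correlate")
  sta <- colSums(stimuli * spikes) / sum(spikes)
  sta - colMeans(stimuli)
}
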