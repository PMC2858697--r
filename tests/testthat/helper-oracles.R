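# central-difference derivative of a scalar function
fd_central <- function(f, x, h = 1e-6 * max(1, abs(x))) {
  (f(x + h) - f(x - h)) / (2 * h)
}

# relative error, guarded against zero denominators
rel_err <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)

# empirical KL of samples to Exp(mu) over equal-probability bins (independent
# of the package's estimator implementation details)
kl_to_exp <- function(x, mu, n_bins = 50) {
  edges <- stats::qexp(seq(0, 1, length.out = n_bins + 1), rate = 1 / mu)
  edges[1] <- -Inf; edges[n_bins + 1] <- Inf
  ph <- tabulate(findInterval(x, edges, rightmost.closed = TRUE), n_bins) / length(x)
  sum(ifelse(ph > 0, ph * log(ph * n_bins), 0))
}

excess_kurtosis <- function(x) mean((x - mean(x))^4) / stats::var(x)^2 - 3
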