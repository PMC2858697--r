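test_that("demixing weight projection uses the dominant channel with the right sign", {
  expect_equal(project_demix_weights(c(1, 0, 0, 0)), c(1, 0))
  # swapping on/off of one dimension flips that component's sign exactly
  w <- c(0.8, 0.2, 0.1, 0.6)
  v <- project_demix_weights(w)
  v_sw <- project_demix_weights(c(0.2, 0.8, 0.1, 0.6))
  expect_equal(v_sw[1], -v[1])
  expect_equal(v_sw[2], v[2])
  # ties break toward +
  expect_equal(project_demix_weights(c(0.5, 0.5, 1, 0))[1], 0.5)
  expect_error(project_demix_weights(c(0, 0, 0, 0)), "zero")
  expect_error(project_demix_weights(c(-1, 0, 0, 0)), "nonnegative")
})

test_that("the projection matches brute-force minimum-error optimization in direction", {
  # oracle: minimize || w - enc(v) ||^2 over 2-D v, where enc places the
  # rectified parts of v on the on/off channels
  enc <- function(v) c(max(v[1], 0), max(-v[1], 0), max(v[2], 0), max(-v[2], 0))
  set.seed(12)
  for (i in 1:30) {
    w <- stats::runif(4)
    obj <- function(v) sum((w - enc(v))^2)
    # multi-start over the four sign quadrants (the objective is piecewise
    # smooth, one region per sign pattern)
    fits <- lapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)), function(s)
      stats::optim(0.3 * s, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 5000)))
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
    v_hat <- project_demix_weights(w)
    cosine <- sum(best$par * v_hat) / sqrt(sum(best$par^2) * sum(v_hat^2))
    expect_gt(cosine, 0.99)
    expect_lte(obj(v_hat), best$value + 1e-8)
  }
})

test_that("angle estimation folds into the requested modulus and ignores scale", {
  expect_equal(estimate_angle(c(1, 0)), 0)
  expect_equal(estimate_angle(c(-1, -1), modulus = pi), pi / 4, tolerance = 1e-12)
  v <- c(0.3, 0.8)
  expect_equal(estimate_angle(v), estimate_angle(10 * v), tolerance = 1e-12)
  a <- estimate_angle(c(-0.2, 0.9), modulus = pi / 2)
  expect_gte(a, 0); expect_lt(a, pi / 2)
  expect_error(estimate_angle(c(0, 0)), "zero")
})

test_that("on/off receptive fields are the signed channel difference", {
  w_on <- matrix(1:4, 2); w_off <- matrix(c(0, 1, 1, 5), 2)
  expect_equal(rf_from_onoff(w_on, w_off), w_on - w_off)
  expect_equal(rf_from_onoff(w_on, w_on), matrix(0, 2, 2))
  expect_equal(rf_from_onoff(w_off, w_on), -(w_on - w_off))
  expect_error(rf_from_onoff(w_on, matrix(0, 3, 3)), "shape")
})

test_that("bar counting classifies templates, flat fields and noisy templates correctly", {
  cfg <- bars_config(grid = 5)
  tmpl <- bar_templates(cfg)
  for (b in c(1, 4, 8)) {
    cb <- count_bars(tmpl[[b]] * 2.5, cfg)
    expect_equal(cb$count, 1L)
    expect_equal(cb$bars, b)
  }
  # uniform field: threshold excludes nothing, no bar-like structure
  expect_equal(count_bars(matrix(1, 5, 5), cfg)$count, 0L)
  expect_equal(count_bars(matrix(0, 5, 5), cfg)$count, 0L)
  # two disjoint bars both present
  two <- tmpl[[1]] + tmpl[[3]]
  expect_equal(sort(count_bars(two, cfg)$bars), c(1L, 3L))
  # template plus 5% noise: still exactly one bar in >= 99/100 draws
  set.seed(14)
  hits <- 0
  for (i in 1:100) {
    noisy <- tmpl[[2]] + matrix(abs(stats::rnorm(25, 0, 0.05)), 5, 5)
    if (count_bars(noisy, cfg)$count == 1) hits <- hits + 1
  }
  expect_gte(hits, 99)
})

test_that("bar counting is covariant under the grid's relabeling symmetries", {
  cfg <- bars_config(grid = 5)
  tmpl <- bar_templates(cfg)
  f <- tmpl[[2]] * 1.7  # horizontal bar, row 2
  # transpose maps horizontal bar j to vertical bar j
  expect_equal(count_bars(t(f), cfg)$bars, 7L)
  # vertical flip maps row r to row 6 - r
  expect_equal(count_bars(f[5:1, ], cfg)$bars, 4L)
})

test_that("output statistics recover the exponential moments and flag degenerate input", {
  set.seed(15)
  x <- stats::rexp(1e5, rate = 1 / 5)
  st <- output_stats(x, mu_goal = 5)
  expect_equal(st$mean, 5, tolerance = 0.05)
  expect_gt(st$cv, 0.98); expect_lt(st$cv, 1.02)
  expect_lt(abs(st$excess_kurtosis - 6), 0.5)
  expect_lt(st$kl, 0.01)
  # KL is invariant under reordering
  expect_equal(output_stats(rev(x), 5)$kl, st$kl)
  expect_warning(st0 <- output_stats(rep(3, 2000), 5), "constant")
  expect_equal(st0$cv, 0)
  expect_true(is.na(st0$kl))
})

test_that("normalized mutual information has its deterministic and independent limits", {
  x <- rep(c(1, 5), each = 500)
  expect_equal(normalized_mi(x, x, n_bins = 2), 1)
  expect_equal(normalized_mi(x, 6 - x, n_bins = 2), 1)  # one-to-one relation
  set.seed(16)
  a <- stats::runif(1e4); b <- stats::runif(1e4)
  expect_lt(normalized_mi(a, b, n_bins = 10), 0.02)
  expect_gte(normalized_mi(a, a), 0.99)
})

test_that("windowed decorrelation metrics fall in range and skip degenerate neurons", {
  set.seed(17)
  shared <- stats::rnorm(400)
  rates <- rbind(shared + 0.1 * stats::rnorm(400),
                 shared + 0.1 * stats::rnorm(400),
                 stats::rnorm(400))
  dm <- decorrelation_metrics(rates, window = 200)
  expect_equal(nrow(dm), 2L)
  expect_true(all(dm$mean_abs_r >= 0 & dm$mean_abs_r <= 1))
  expect_true(all(dm$mean_nmi >= 0 & dm$mean_nmi <= 1))
  expect_equal(dm$n_pairs, c(3L, 3L))
  # a constant neuron is skipped, leaving one valid pair
  rates2 <- rbind(shared, shared * 2, rep(1, 400))
  dm2 <- decorrelation_metrics(rates2, window = 400)
  expect_equal(dm2$n_pairs, 1L)
})

test_that("reverse correlation recovers the linear filter direction from white noise", {
  set.seed(18)
  n <- 4000
  stim <- matrix(stats::rnorm(n * 9), n, 9)
  w <- c(3, 2, 1, 0, 0, 0, -1, -2, -3)
  drive <- as.numeric(stim %*% w)
  lambda <- pmax(drive, 0) * 0.5
  spikes <- stats::rpois(n, lambda)
  sta <- reverse_correlation(stim, spikes)
  cosine <- sum(sta * w) / sqrt(sum(sta^2) * sum(w^2))
  expect_gt(cosine, 0.8)
  # doubling contrast leaves the direction unchanged
  sta2 <- reverse_correlation(2 * stim, spikes)
  cos12 <- sum(sta * sta2) / sqrt(sum(sta^2) * sum(sta2^2))
  expect_gt(cos12, 0.99)
  # spikes independent of the stimulus: STA norm below 3 SE of the null
  spikes0 <- stats::rpois(n, 1)
  sta0 <- reverse_correlation(stim, spikes0)
  null_se <- 1 / sqrt(sum(spikes0))
  expect_lt(sqrt(mean(sta0^2)), 3 * null_se)
  expect_error(reverse_correlation(stim, rep(0, n)), "no spikes")
  expect_error(reverse_correlation(matrix(1, 10, 3), rep(1, 10)), "constant")
})

test_that("population bar assignment counts distinct recovered basis elements", {
  cfg <- bars_config(grid = 4, bar_width = 2)
  tmpl <- bar_templates(cfg)
  expect_length(tmpl, 4)
  rf1 <- tmpl[[1]] * 2
  a1 <- assign_rf_to_bar(rf1, cfg)
  expect_true(a1$exact); expect_equal(a1$bar, 1L)
  # an incomplete bar still assigns by weight concentration
  rf2 <- tmpl[[3]] * 2; rf2[1, 1] <- 0
  a2 <- assign_rf_to_bar(rf2, cfg)
  expect_false(a2$exact); expect_equal(a2$bar, 3L)
})
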