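test_that("Laplacian source pairs have unit variance, kurtosis 3 and independent components", {
  set.seed(1)
  s <- sample_laplace_pair(1e6)
  v <- apply(s, 2, stats::var)
  expect_true(all(v > 0.99 & v < 1.01))
  k <- apply(s, 2, excess_kurtosis)
  expect_true(all(abs(k - 3) < 0.1))
  expect_lt(abs(stats::cor(s)[1, 2]), 0.005)
})

test_that("rotation mixing preserves norms and has the axis special cases", {
  expect_equal(mix_rotate(c(1.5, -2), 0), c(1.5, -2))
  expect_equal(mix_rotate(c(1.5, -2), pi / 2), c(2, 1.5), tolerance = 1e-12)
  set.seed(2)
  s <- sample_laplace_pair(100)
  x <- mix_rotate(s, 0.7)
  expect_equal(rowSums(x^2), rowSums(s^2), tolerance = 1e-12)
})

test_that("on/off encoding rectifies exactly and reconstructs the signal", {
  expect_equal(onoff_encode(c(1.5, -0.3)), c(1.5, 0, 0, 0.3))
  expect_equal(onoff_encode(c(0, 0)), c(0, 0, 0, 0))
  set.seed(3)
  x <- matrix(stats::rnorm(200), 100, 2)
  e <- onoff_encode(x)
  expect_true(all(e >= 0))
  expect_true(all(e[, 1] * e[, 2] == 0) && all(e[, 3] * e[, 4] == 0))
  expect_equal(e[, 1] - e[, 2], x[, 1])
  expect_equal(e[, 3] - e[, 4], x[, 2])
})

test_that("Poisson spike trains match their rates and are independent across synapses", {
  set.seed(4)
  expect_equal(sum(poisson_trains(0, 1000, 1)), 0)
  tr <- poisson_trains(20, 1000 * 1000, 1)  # one synapse, 1000 s
  count <- sum(tr)
  expect_lt(abs(count - 20000), 3 * sqrt(20000))
  # two synapses of one channel: uncorrelated indicators
  tr2 <- poisson_trains(20, 5e5, 1, n_per_channel = 2)
  expect_lt(abs(stats::cor(tr2[, 1], tr2[, 2])), 0.01)
  expect_error(poisson_trains(2000, 100, 1), "one spike per bin")
})

test_that("spike matrices export to ordered two-column rasters", {
  m <- matrix(0L, 4, 2)
  m[2, 1] <- 1L; m[4, 1] <- 1L; m[1, 2] <- 1L
  df <- raster_to_df(m, dt = 2)
  expect_equal(df$channel_id, c(1, 1, 2))
  expect_equal(df$spike_time_ms, c(3, 7, 1))
})

test_that("bars samples are OR superpositions with the correct basis geometry", {
  cfg <- bars_config(grid = 5, bar_width = 1)
  tmpl <- bar_templates(cfg)
  expect_length(tmpl, 10)
  expect_true(all(vapply(tmpl, sum, numeric(1)) == 5))
  cfg2 <- bars_config(grid = 10, bar_width = 2)
  expect_length(bar_templates(cfg2), 10)
  expect_true(all(vapply(bar_templates(cfg2), sum, numeric(1)) == 20))
  expect_error(bars_config(grid = 5, bar_width = 2), "even")
  # independent mode with p = 0: empty grid
  set.seed(5)
  s0 <- bars_sample(bars_config(grid = 5, mode = "independent_p", p = 0))
  expect_equal(sum(s0$grid), 0)
  # exactly-k mode always draws k distinct bars and ORs their templates
  cfg4 <- bars_config(grid = 5, mode = "exactly_k", k = 4)
  for (i in 1:20) {
    s4 <- bars_sample(cfg4)
    expect_length(unique(s4$bars), 4L)
    manual <- Reduce(`|`, bar_templates(cfg4)[s4$bars]) * 1L
    expect_equal(s4$grid, manual)
  }
})

test_that("center-pixel activation probability matches brute-force subset enumeration", {
  # 3x3 grid, 1-px bars, 6 bars, p = 0.5: enumerate all 2^6 bar subsets
  cfg <- bars_config(grid = 3, mode = "independent_p", p = 0.5)
  tmpl <- bar_templates(cfg)
  n_bars <- length(tmpl)
  p_on <- 0
  for (mask in 0:(2^n_bars - 1)) {
    ids <- which(bitwAnd(mask, 2^(seq_len(n_bars) - 1)) > 0)
    grid <- if (length(ids)) Reduce(`|`, tmpl[ids]) * 1L else matrix(0L, 3, 3)
    p_on <- p_on + (0.5^n_bars) * grid[2, 2]
  }
  expect_equal(p_on, 0.75, tolerance = 1e-12)
  set.seed(6)
  hits <- mean(replicate(4000, bars_sample(cfg)$grid[2, 2]))
  expect_lt(abs(hits - p_on), 3 * sqrt(0.75 * 0.25 / 4000))
})

test_that("bars-to-rates normalization maps single bars to nu_max and empty grids to background", {
  cfg <- bars_config(grid = 5, nu_bg = 2, nu_max = 40)
  tmpl <- bar_templates(cfg)
  expect_equal(unique(as.numeric(bars_to_rates(matrix(0L, 5, 5), cfg))), 2)
  r1 <- bars_to_rates(tmpl[[1]], cfg)
  expect_equal(sort(unique(as.numeric(r1))), c(2, 40))
  # two disjoint equal bars: bar pixels at nu_bg + (nu_max-nu_bg)/sqrt(2)
  two <- (tmpl[[1]] | tmpl[[2]]) * 1L
  r2 <- bars_to_rates(two, cfg)
  expect_equal(max(r2), 2 + 38 / sqrt(2), tolerance = 1e-12)
})

test_that("dichotomous-Gaussian solver hits the target correlation", {
  sol0 <- solve_dichotomous_gaussian(10, 0, 1)
  expect_equal(sol0$lam, 0)
  expect_equal(sol0$gamma, stats::qnorm(1 - 0.01), tolerance = 1e-12)
  # comonotone limit
  solhi <- solve_dichotomous_gaussian(10, 0.999, 1)
  expect_gt(solhi$lam, 0.999)
  # p = 0.01, c = 0.5: empirical indicator correlation 0.5 +- 0.02
  sol <- solve_dichotomous_gaussian(10, 0.5, 1)
  set.seed(7)
  n <- 1e6
  zc <- stats::rnorm(n)
  z1 <- sqrt(sol$lam) * zc + sqrt(1 - sol$lam) * stats::rnorm(n)
  z2 <- sqrt(sol$lam) * zc + sqrt(1 - sol$lam) * stats::rnorm(n)
  r <- stats::cor(z1 > sol$gamma, z2 > sol$gamma)
  expect_lt(abs(r - 0.5), 0.02)
})

test_that("correlated spike trains match rate and correlation targets within and across sets", {
  spec <- correlation_spec(20, 0.5, member_sets = list(1:5, 6:8), n_channels = 12)
  set.seed(8)
  tr <- correlated_trains(spec, 1e5)  # 100 s
  rates <- colMeans(tr) * 1000
  se <- sqrt(20 / 1e5) * 1000 / sqrt(1000)  # 3-sigma band ~ 1.3 Hz
  expect_true(all(abs(rates - 20) < 3 * sqrt(0.02 * 0.98 / 1e5) * 1000))
  cc <- stats::cor(tr[, 1:5])
  expect_lt(max(abs(cc[upper.tri(cc)] - 0.5)), 0.02)
  cross <- stats::cor(tr[, 3], tr[, 10])
  expect_lt(abs(cross), 0.01)
  # c = 0 reduces to independent Poisson: per-bin counts are binomial
  spec0 <- correlation_spec(20, 0, member_sets = list(1:5), n_channels = 5)
  tr0 <- correlated_trains(spec0, 5e4)
  counts <- pmin(rowSums(tr0), 2)  # pool rare bins with >= 2 joint spikes
  probs <- c(stats::dbinom(0:1, 5, 0.02), 1 - sum(stats::dbinom(0:1, 5, 0.02)))
  pval <- stats::chisq.test(table(factor(counts, levels = 0:2)),
                            p = probs)$p.value
  expect_gt(pval, 0.01)
  expect_error(correlation_spec(20, 0.5, list(1:3, 3:5), 10), "disjoint")
})

test_that("image preprocessing removes DC, rejects flat patches and rectifies into on/off maps", {
  expect_error(preprocess_image_patches(matrix(1, 64, 64), n_patches = 3),
               "contrast")
  set.seed(9)
  img <- synthetic_test_image(96)
  patches <- preprocess_image_patches(img, n_patches = 5, nu_bg = 2, nu_max = 40)
  expect_length(patches, 5)
  for (p in patches) {
    expect_true(all(p$on >= 2) && all(p$off >= 2))
    expect_true(all(p$on <= 40) && all(p$off <= 40))
    # rectification: a pixel is never above background in both maps
    expect_true(all((p$on - 2) * (p$off - 2) == 0))
  }
  # DoG frequency response: DC attenuated to < 1% of the input DC
  const <- matrix(5, 64, 64)
  expect_lt(max(abs(spikeica:::dog_filter_image(const, 1, 3))), 0.01 * 5)
})
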