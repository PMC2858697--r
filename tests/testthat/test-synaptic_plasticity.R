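test_that("STDP kernels reproduce the closed-form single-pair values", {
  p <- stdp_params(A_plus = 0.005, A_minus = 0.0035, tau_plus = 17, tau_minus = 34)
  # post at 10 ms, pre at 20 ms: depression branch
  s <- pairing_state(1, p)
  s <- stdp_on_post(s, 10)$state
  r <- stdp_on_pre(s, 1, 20)
  expect_equal(r$dw, -0.0035 * exp(-10 / 34), tolerance = 1e-12)
  # pre at 10 ms, post at 20 ms: potentiation branch
  s <- pairing_state(1, p)
  expect_equal(stdp_on_pre(s, 1, 10)$dw, 0)  # no post spike yet
  s <- stdp_on_pre(s, 1, 10)$state
  r <- stdp_on_post(s, 20)
  expect_equal(r$dw, 0.005 * exp(-10 / 17), tolerance = 1e-12)
  # isolated post with no prior pre: no potentiation anywhere
  s <- pairing_state(3, p)
  expect_equal(stdp_on_post(s, 5)$dw, c(0, 0, 0))
  # time regression errors
  s <- stdp_on_post(pairing_state(1, p), 10)$state
  expect_error(stdp_on_post(s, 5), "nondecreasing")
})

test_that("simultaneous pre/post spikes contribute nothing and carry to the next pairing", {
  p <- stdp_params(A_plus = 0.005, A_minus = 0.0035, tau_plus = 17, tau_minus = 34)
  s <- pairing_state(1, p)
  s <- stdp_on_pre(s, 1, 10)$state
  r <- stdp_on_post(s, 10)       # dt = 0: no change
  expect_equal(r$dw, 0)
  r2 <- stdp_on_post(r$state, 15)  # the pre at 10 pairs with this later post
  expect_equal(r2$dw, 0.005 * exp(-5 / 17), tolerance = 1e-12)
})

test_that("nearest-neighbor and all-to-all pairings differ exactly as hand enumeration dictates", {
  A <- stdp_params(A_plus = 0.005, A_minus = 0.0035, tau_plus = 17, tau_minus = 34)
  run_train <- function(mode) {
    p <- stdp_params(A_plus = A$A_plus, A_minus = A$A_minus,
                     tau_plus = A$tau_plus, tau_minus = A$tau_minus, mode = mode)
    s <- pairing_state(1, p)
    dw <- 0
    # quadruplet: pre 0, post 5, post 15, pre 25
    s1 <- stdp_on_pre(s, 1, 0);   dw <- dw + s1$dw; s <- s1$state
    s2 <- stdp_on_post(s, 5);     dw <- dw + s2$dw; s <- s2$state
    s3 <- stdp_on_post(s, 15);    dw <- dw + s3$dw; s <- s3$state
    s4 <- stdp_on_pre(s, 1, 25);  dw <- dw + s4$dw; s <- s4$state
    dw
  }
  # nearest (presynaptic-centered): pre0 pairs with its nearest following
  # post (5) only; pre25 pairs with nearest preceding post (15)
  nn_expected <- A$A_plus * exp(-5 / 17) - A$A_minus * exp(-10 / 34)
  # all-to-all: pre0 with both posts; pre25 with both posts
  aa_expected <- A$A_plus * (exp(-5 / 17) + exp(-15 / 17)) -
    A$A_minus * (exp(-20 / 34) + exp(-10 / 34))
  expect_equal(run_train("nearest"), nn_expected, tolerance = 1e-12)
  expect_equal(run_train("all_to_all"), aa_expected, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(nn_expected, aa_expected)))
})

test_that("the two pairing modes agree on trains with at most one pre and one post spike", {
  for (times in list(c(pre = 3, post = 12), c(pre = 20, post = 4))) {
    dws <- vapply(c("nearest", "all_to_all"), function(mode) {
      s <- pairing_state(1, stdp_params(mode = mode))
      dw <- 0
      ev <- sort(times)
      for (nm in names(ev)) {
        r <- if (nm == "pre") stdp_on_pre(s, 1, ev[[nm]]) else stdp_on_post(s, ev[[nm]])
        dw <- dw + sum(r$dw); s <- r$state
      }
      dw
    }, numeric(1))
    expect_equal(dws[["nearest"]], dws[["all_to_all"]], tolerance = 1e-12)
  }
})

test_that("triplet mode reduces to the pair rule at A3 = 0 and adds the slow-trace term", {
  set.seed(2)
  pre_t <- sort(stats::runif(30, 0, 500))
  post_t <- sort(stats::runif(20, 0, 500))
  run_mode <- function(p) {
    s <- pairing_state(1, p)
    ev <- rbind(data.frame(t = pre_t, pre = TRUE), data.frame(t = post_t, pre = FALSE))
    ev <- ev[order(ev$t, ev$pre), ]  # post processed before a same-time pre
    dw <- 0
    for (i in seq_len(nrow(ev))) {
      r <- if (ev$pre[i]) stdp_on_pre(s, 1, ev$t[i]) else stdp_on_post(s, ev$t[i])
      dw <- dw + sum(r$dw); s <- r$state
    }
    dw
  }
  pair <- run_mode(stdp_params(mode = "nearest"))
  trip0 <- run_mode(stdp_params(mode = "triplet", A3_plus = 0))
  trip1 <- run_mode(stdp_params(mode = "triplet", A3_plus = 0.005))
  expect_equal(trip0, pair, tolerance = 1e-12)
  expect_gt(trip1, pair)  # extra potentiation from the slow post trace
})

test_that("clipping at zero is elementwise, idempotent and shape-preserving", {
  expect_equal(clip_nonnegative(c(-0.1, 0.2)), c(0, 0.2))
  w <- matrix(c(0.5, -1, 2, 0), 2)
  expect_equal(clip_nonnegative(clip_nonnegative(w)), clip_nonnegative(w))
  expect_equal(dim(clip_nonnegative(w)), c(2L, 2L))
  expect_equal(clip_nonnegative(c(1, 2)), c(1, 2))
})

test_that("synaptic scaling normalizes each scope exactly and flags dead scopes", {
  cfg <- scaling_config(W_total = 1, norm_order = "L1")
  expect_equal(scale_weights(c(2, 2), cfg), c(0.5, 0.5))
  # already normalized: unchanged to 1e-12
  expect_equal(scale_weights(c(0.3, 0.7), cfg), c(0.3, 0.7), tolerance = 1e-12)
  # two scopes normalized independently regardless of imbalance
  cfg2 <- scaling_config(W_total = 1, scope = "per_population")
  w <- scale_weights(c(10, 30, 0.1, 0.3), cfg2,
                     population_masks = list(1:2, 3:4))
  expect_equal(sum(w[1:2]), 1, tolerance = 1e-12)
  expect_equal(sum(w[3:4]), 1, tolerance = 1e-12)
  expect_error(scale_weights(c(0, 0, 0), scaling_config(W_total = 1)), "dead scope")
  # L2 scaling
  cfgL2 <- scaling_config(W_total = 2, norm_order = "L2")
  w2 <- scale_weights(c(3, 4), cfgL2)
  expect_equal(sqrt(sum(w2^2)), 2, tolerance = 1e-12)
})

test_that("the saturation bound pins winners while preserving the scope total", {
  cfg <- scaling_config(W_total = 10, w_max = 2)
  w <- scale_weights(c(9, 5, 1, 1, 0.5), cfg)
  expect_equal(sum(w), 10, tolerance = 1e-9)
  expect_true(all(w <= 2 + 1e-12))
  expect_equal(w[1], 2)
  expect_equal(w[2], 2)
})

test_that("expected nearest-neighbor drift has the stated structure", {
  p <- stdp_params(A_plus = 0.005, A_minus = 0.0035, tau_plus = 17, tau_minus = 34)
  expect_equal(expected_drift_nn(10, 0, p), 0)
  expect_equal(expected_drift_nn(0, 10, p), 0)
  # proportional to the presynaptic rate
  d <- expected_drift_nn(c(5, 10, 20), 10, p)
  expect_equal(d[2] / d[1], 2, tolerance = 1e-9)
  expect_equal(d[3] / d[1], 4, tolerance = 1e-9)
})

test_that("Monte-Carlo drift matches the closed form for independent Poisson trains", {
  set.seed(31)
  p <- stdp_params(A_plus = 0.005, A_minus = 0.0035, tau_plus = 17, tau_minus = 34)
  for (rates in list(c(10, 10), c(10, 60))) {
    mc <- stdp_drift_mc(rates[1], rates[2], p, duration = 400, n_rep = 16)
    cf <- expected_drift_nn(rates[1], rates[2], p)
    expect_lt(abs(mc$drift - cf), 3 * mc$se)
  }
})

test_that("the BCM threshold formula, regime conditions and drift sign change are consistent", {
  p <- stdp_params(A_plus = 0.01, A_minus = 0.006, tau_plus = 20, tau_minus = 40)
  expect_true(is_bcm_regime(p))
  th <- bcm_threshold(p)
  expect_equal(th, 12.5, tolerance = 1e-9)
  # root of the closed-form drift located by bisection agrees within 10%
  root <- stats::uniroot(function(r) expected_drift_nn(10, r, p), c(1, 500))$root
  expect_lt(abs(root - th) / th, 0.1)
  # numerator vanishing: threshold zero
  p0 <- stdp_params(A_plus = 0.01, A_minus = 0.005, tau_plus = 20, tau_minus = 40)
  expect_equal(bcm_threshold(p0), 0)
  # violated conditions are named
  expect_error(bcm_threshold(stdp_params(A_plus = 0.005, A_minus = 0.006)),
               "A_plus > A_minus")
  expect_error(bcm_threshold(stdp_params(A_plus = 0.01, A_minus = 0.0051,
                                         tau_plus = 39, tau_minus = 40)),
               "tau_minus")
  # Monte-Carlo drift changes sign across the threshold
  set.seed(17)
  below <- stdp_drift_mc(10, th / 2, p, duration = 400, n_rep = 16)
  above <- stdp_drift_mc(10, 2 * th, p, duration = 400, n_rep = 16)
  expect_lt(below$drift + 3 * below$se, 0)
  expect_gt(above$drift - 3 * above$se, 0)
})

test_that("event-driven pairing functions agree with the vectorized drift accumulator", {
  # same Poisson realization pushed through both code paths
  set.seed(41)
  p <- stdp_params(A_plus = 0.005, A_minus = 0.0035, tau_plus = 17, tau_minus = 34)
  pre_t <- sort(stats::runif(200, 0, 1e4))
  post_t <- sort(stats::runif(150, 0, 1e4))
  s <- pairing_state(1, p)
  ev <- rbind(data.frame(t = pre_t, pre = TRUE), data.frame(t = post_t, pre = FALSE))
  ev <- ev[order(ev$t, ev$pre), ]
  dw_event <- 0
  for (i in seq_len(nrow(ev))) {
    r <- if (ev$pre[i]) stdp_on_pre(s, 1, ev$t[i]) else stdp_on_post(s, ev$t[i])
    dw_event <- dw_event + sum(r$dw); s <- r$state
  }
  # vectorized accumulation as in the Monte-Carlo oracle (times in seconds)
  pre_s <- pre_t / 1000; post_s <- post_t / 1000
  tp <- p$tau_plus / 1000; tm <- p$tau_minus / 1000
  idx <- findInterval(pre_s, post_s)
  ltd <- -p$A_minus * sum(exp(-(pre_s[idx >= 1] - post_s[idx[idx >= 1]]) / tm))
  nxt <- idx + 1; ok <- nxt <= length(post_s)
  ltp <- p$A_plus * sum(exp(-(post_s[nxt[ok]] - pre_s[ok]) / tp))
  expect_equal(dw_event, ltp + ltd, tolerance = 1e-9)
})
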