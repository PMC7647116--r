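test_that("KS statistic matches a brute-force empirical-CDF computation", {
  set.seed(3)
  for (i in 1:5) {
    a <- rnorm(40 + i)
    b <- rnorm(35, mean = runif(1, 0, 2))
    expect_equal(ks_two_sample(a, b)$D, ks_oracle(a, b), tolerance = 1e-12)
  }
  x <- rnorm(30)
  expect_equal(ks_two_sample(x, x)$D, 0)
  expect_equal(ks_two_sample(rnorm(30), rnorm(30) + 100)$D, 1)
  expect_error(ks_two_sample(numeric(0), rnorm(3)), "non-empty")
})

test_that("KL estimator matches a direct discrete sum and is non-negative", {
  # fixed histograms: samples placed to give known bin counts
  obs <- c(0.1, 0.1, 0.9, 0.9, 0.9, 0.5)
  pred <- c(0.1, 0.5, 0.5, 0.9)
  bins <- 2
  # shared range [0.1, 0.9], 2 bins ([0.1, 0.5), [0.5, 0.9]); add-one smoothed
  p <- (c(2, 4) + 1) / 8
  q <- (c(1, 3) + 1) / 6
  expect_equal(kl_press_time_divergence(obs, pred, bins = bins),
               sum(p * log(p / q)), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:5) {
    a <- rlnorm(300, 0, 0.3)
    b <- rlnorm(300, 0.2, 0.3)
    expect_gte(kl_press_time_divergence(a, b), 0)
  }
  same <- rlnorm(5000, 0, 0.3)
  expect_lt(kl_press_time_divergence(same, same), 0.01)
})

test_that("KL shrinks as the predictive approaches the observed distribution", {
  set.seed(5)
  obs <- rlnorm(2000, 0, 0.3)
  near <- rlnorm(2000, 0.05, 0.3)
  far <- rlnorm(2000, 0.5, 0.3)
  expect_lt(kl_press_time_divergence(obs, near),
            kl_press_time_divergence(obs, far))
})

test_that("change-point model finds a planted change and honours symmetry", {
  set.seed(6)
  y <- c(rnorm(6, 2.2, 0.3), rnorm(44, 0.9, 0.3))
  cp <- change_point_fit(y)
  expect_equal(cp$tau_map, 6)
  expect_false(cp$diffuse)
  expect_gt(cp$mu_before, cp$mu_after)
  expect_equal(sum(cp$tau_posterior$probability), 1, tolerance = 1e-12)
  # reversed series: change detected at the mirrored position
  cp_rev <- change_point_fit(rev(y))
  expect_equal(cp_rev$tau_map, length(y) - 6)
  expect_lt(cp_rev$mu_before, cp_rev$mu_after)
  expect_error(change_point_fit(c(1, 2)), "at least 3")
})

test_that("a constant series yields a diffuse change-point posterior", {
  set.seed(7)
  y <- rnorm(40, 1.5, 0.001)
  cp <- suppressMessages(change_point_fit(y))
  expect_true(cp$diffuse)
  expect_lt(max(cp$tau_posterior$probability), 0.2)
})

test_that("product space returns the prior odds with no data and is seeded", {
  trials <- feedback_trials(seed = 61, n_trials = 30)
  spn <- quick_spec("newtonian", sigma_x_fixed = 0.05)
  spl <- quick_spec("linear", sigma_x_fixed = 0.05)
  K0 <- product_space_bayes_factor(trials[0, ], spn, spl, seed = 1)
  expect_equal(K0$K, 1)
  k1 <- product_space_bayes_factor(trials, spn, spl, seed = 2,
                                   iterations = 300, warmup = 100,
                                   pilot_iterations = 300)
  k2 <- product_space_bayes_factor(trials, spn, spl, seed = 2,
                                   iterations = 300, warmup = 100,
                                   pilot_iterations = 300)
  expect_equal(k1$K, k2$K)
  expect_equal(sum(k1$visits), 300)
})

test_that("the generating class wins the product-space comparison", {
  spn <- quick_spec("newtonian", sigma_x_fixed = 0.05)
  spl <- quick_spec("linear", sigma_x_fixed = 0.05)
  tn <- feedback_trials("newtonian", seed = 62, n_trials = 100)
  tl <- feedback_trials("linear", seed = 63, n_trials = 100)
  Kn <- product_space_bayes_factor(tn, spn, spl, seed = 3,
                                   iterations = 600, warmup = 150,
                                   pilot_iterations = 500)
  Kl <- product_space_bayes_factor(tl, spn, spl, seed = 3,
                                   iterations = 600, warmup = 150,
                                   pilot_iterations = 500)
  expect_gt(Kn$K, 1)
  expect_lt(Kl$K, 1)
  # relabelling invariance: the two one-sided odds are reciprocal by
  # construction of the index posterior
  odds <- (Kn$visits[["newtonian"]] + 0.5) / (Kn$visits[["linear"]] + 0.5)
  expect_equal(Kn$K, unname(odds))
})

test_that("bayes factor reports carry the evidence band interpretation", {
  r_strong <- noisynewton:::bf_report(10, c(newtonian = 100L, linear = 0L), TRUE)
  expect_match(r_strong$interpretation, "substantial \\(newtonian\\)")
  expect_match(r_strong$interpretation, "bound")
  r_weak <- noisynewton:::bf_report(0.5, c(newtonian = 10L, linear = 20L), FALSE)
  expect_match(r_weak$interpretation, "anecdotal \\(linear\\)")
  expect_equal(r_strong$evidence_band, 3.2)
})
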