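two_pucks <- c("yellow-diamond" = 1.5, "red-dots" = 2.0)

oracle_log_joint_obs <- function(events, lat, spec) {
  sv <- spec$sigma_vel
  mF <- unname(lat$mF[as.character(events$known_puck_id)])
  pred <- collision_oracle_vec(lat$vF_per, lat$vNF_per, mF, lat$mNF)
  pr <- spec$prior_mass_NF
  lp <- sum(dlnorm(lat$vF_per, log(events$vF) + sv^2, sv, log = TRUE)) +
    sum(dlnorm(lat$vNF_per, log(events$vNF) + sv^2, sv, log = TRUE)) +
    sum(dlnorm(events$uF, log(pred$uF) + sv^2, sv, log = TRUE)) +
    sum(dlnorm(events$uNF, log(pred$uNF) + sv^2, sv, log = TRUE)) +
    dgamma(lat$mNF, pr[1], pr[2], log = TRUE)
  for (p in names(lat$mF)) {
    g <- spec$prior_mass_F[[p]]
    lp <- lp + dgamma(lat$mF[[p]], g[1], g[2], log = TRUE)
  }
  lp
}

collision_oracle_vec <- function(vF, vNF, mF, mNF) {
  uF <- numeric(length(vF))
  uNF <- numeric(length(vF))
  for (i in seq_along(vF)) {
    o <- collision_oracle(vF[i], vNF[i], mF[i], mNF)
    uF[i] <- o$uF
    uNF[i] <- o$uNF
  }
  list(uF = uF, uNF = uNF)
}

test_that("observation log joint matches an independent density oracle", {
  ev <- generate_collisions(2.5, two_pucks, seed = 51, n_collisions = 8)
  spec <- observation_spec(
    prior_mass_F = list("yellow-diamond" = c(9, 6), "red-dots" = c(16, 8))
  )
  set.seed(4)
  for (s in 1:4) {
    lat <- list(
      vF_per = ev$vF * exp(rnorm(8, 0, 0.1)),
      vNF_per = ev$vNF * exp(rnorm(8, 0, 0.1)),
      mNF = runif(1, 1.5, 3.5),
      mF = c("yellow-diamond" = runif(1, 1, 2), "red-dots" = runif(1, 1.5, 2.5))
    )
    expect_equal(log_joint_observation(ev, lat, spec),
                 oracle_log_joint_obs(ev, lat, spec),
                 tolerance = 1e-10)
  }
  bad <- list(vF_per = ev$vF, vNF_per = ev$vNF, mNF = -1)
  expect_identical(log_joint_observation(ev, bad, spec), -Inf)
})

test_that("observation log joint factorises over collisions", {
  ev <- generate_collisions(2.5, two_pucks, seed = 52, n_collisions = 6)
  spec <- observation_spec()
  lat <- list(vF_per = ev$vF, vNF_per = ev$vNF, mNF = 2.2)
  lat5 <- list(vF_per = ev$vF[-6], vNF_per = ev$vNF[-6], mNF = 2.2)
  delta <- log_joint_observation(ev, lat, spec) -
    log_joint_observation(ev[-6, ], lat5, spec)
  one <- ev[6, ]
  sv <- spec$sigma_vel
  pred <- elastic_collision(one$vF, one$vNF, one$mF, 2.2)
  expect_equal(delta,
               dlnorm(one$vF, log(one$vF) + sv^2, sv, log = TRUE) +
                 dlnorm(one$vNF, log(one$vNF) + sv^2, sv, log = TRUE) +
                 dlnorm(one$uF, log(pred$uF) + sv^2, sv, log = TRUE) +
                 dlnorm(one$uNF, log(pred$uNF) + sv^2, sv, log = TRUE),
               tolerance = 1e-10)
})

test_that("with vanishing percept noise the unknown mass is identified", {
  ev <- generate_collisions(2.5, two_pucks, seed = 53)
  spec <- observation_spec(sigma_vel = 0.02,
                           prior_mass_NF = c(shape = 4, rate = 1.6),
                           seed = 3)
  fit <- suppressWarnings(fit_observation(ev[1:4, ], spec))
  expect_equal(fit$summary$mean, 2.5, tolerance = 0.05)
})

test_that("observation fits are reproducible and recover the mass", {
  ev <- generate_collisions(2.5, two_pucks, seed = 54)
  spec <- observation_spec(seed = 7)
  fit1 <- suppressWarnings(fit_observation(ev, spec))
  fit2 <- suppressWarnings(fit_observation(ev, spec))
  expect_identical(fit1$draws, fit2$draws)
  expect_equal(fit1$summary$mean, 2.5, tolerance = 0.15)
  expect_true(all(fit1$draws$value[fit1$draws$parameter == "mNF"] > 0))
  expect_error(fit_observation(ev[0, ], spec), "at least one")
})

test_that("posterior mean shrinks from the data towards the prior as noise grows", {
  ev <- generate_collisions(2.5, two_pucks, seed = 55)
  prior_off <- c(shape = 100, rate = 100 / 1.8) # confident prior away from truth
  m_lo <- suppressWarnings(fit_observation(
    ev, observation_spec(sigma_vel = 0.05, prior_mass_NF = prior_off, seed = 5)
  ))$summary$mean
  m_hi <- suppressWarnings(fit_observation(
    ev, observation_spec(sigma_vel = 0.6, prior_mass_NF = prior_off, seed = 5)
  ))$summary$mean
  expect_lt(abs(m_lo - 2.5), abs(m_hi - 2.5))
})

test_that("uncertainty trajectory is consistent with single fits", {
  ev <- generate_collisions(2.5, two_pucks, seed = 56)
  spec <- observation_spec(seed = 9)
  traj <- suppressWarnings(uncertainty_trajectory(ev, spec, c(6, 24)))
  expect_equal(traj$n_collisions, c(6, 24))
  single <- suppressWarnings(fit_observation(ev[1:6, ], spec))
  expect_equal(traj$variance[1], single$summary$variance)
  expect_error(uncertainty_trajectory(ev, spec, c(6, 30)), "exceed")
})

test_that("gamma moment matching preserves mean and variance", {
  set.seed(8)
  x <- rgamma(5000, 10, 4)
  g <- as_gamma_prior(x)
  expect_equal(g[["shape"]] / g[["rate"]], mean(x), tolerance = 1e-8)
  expect_equal(g[["shape"]] / g[["rate"]]^2, var(x), tolerance = 1e-8)
  expect_equal(as_gamma_prior(c(3, 2)), c(shape = 3, rate = 2))
})
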