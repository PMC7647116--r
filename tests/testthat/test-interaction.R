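# direct re-statement of the model density, used as the independent oracle
oracle_log_joint <- function(trials, lat, spec) {
  shift <- switch(spec$cost_function,
                  zero_one = lat$sigma_t^2,
                  absolute = 0,
                  quadratic = -lat$sigma_t^2 / 2)
  env <- spec$env
  k <- as.character(trials$puck_id)
  t_int <- if (spec$model_class == "newtonian") {
    (lat$mass[k] / env$interaction_force) *
      sqrt(2 * env$friction_coefficient * env$gravity * lat$x_per)
  } else {
    lat$linear_factor[k] * lat$x_per
  }
  pr <- spec$priors
  par_prior <- if (spec$model_class == "newtonian") pr$mass else pr$linear_factor
  pars <- if (spec$model_class == "newtonian") lat$mass else lat$linear_factor
  sum(dlnorm(trials$t_pre, log(t_int) + shift, lat$sigma_t, log = TRUE)) +
    sum(dlnorm(lat$x_per, log(trials$x) + lat$sigma_x^2, lat$sigma_x, log = TRUE)) +
    sum(dgamma(pars, par_prior[1], par_prior[2], log = TRUE)) +
    dgamma(lat$sigma_t, pr$sigma_t[1], pr$sigma_t[2], log = TRUE) +
    dgamma(lat$sigma_x, pr$sigma_x[1], pr$sigma_x[2], log = TRUE)
}

random_latents <- function(trials, spec, seed) {
  set.seed(seed)
  pucks <- unique(as.character(trials$puck_id))
  lat <- list(
    x_per = trials$x * exp(rnorm(nrow(trials), 0, 0.1)),
    sigma_t = runif(1, 0.1, 0.4),
    sigma_x = runif(1, 0.02, 0.1)
  )
  if (spec$model_class == "newtonian") {
    lat$mass <- setNames(runif(length(pucks), 1, 3), pucks)
  } else {
    lat$linear_factor <- setNames(runif(length(pucks), 0.1, 0.5), pucks)
  }
  lat
}

test_that("log joint matches an independent density evaluation at random points", {
  trials <- feedback_trials(seed = 31, n_trials = 40)
  for (mc_ in c("newtonian", "linear")) {
    for (cf in c("zero_one", "absolute", "quadratic")) {
      spec <- quick_spec(mc_, cf)
      for (s in 1:4) {
        lat <- random_latents(trials, spec, 100 * s)
        expect_equal(log_joint_interaction(trials, lat, spec),
                     oracle_log_joint(trials, lat, spec),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("log joint factorises over trials and rejects out-of-support latents", {
  trials <- feedback_trials(seed = 32, n_trials = 21)
  spec <- quick_spec()
  lat <- random_latents(trials, spec, 5)
  head_lat <- lat
  head_lat$x_per <- lat$x_per[-21]
  delta <- log_joint_interaction(trials, lat, spec) -
    log_joint_interaction(trials[-21, ], head_lat, spec)
  # the difference is exactly the removed trial's likelihood + percept terms
  one <- trials[21, ]
  shift <- -lat$sigma_t^2 / 2
  t_int <- ideal_press_time(lat$x_per[21], lat$mass[as.character(one$puck_id)],
                            spec$env)
  expect_equal(delta,
               dlnorm(one$t_pre, log(t_int) + shift, lat$sigma_t, log = TRUE) +
                 dlnorm(lat$x_per[21], log(one$x) + lat$sigma_x^2, lat$sigma_x,
                        log = TRUE),
               tolerance = 1e-10)
  bad <- lat
  bad$sigma_t <- -0.1
  expect_identical(log_joint_interaction(trials, bad, spec), -Inf)
  bad2 <- lat
  bad2$x_per[3] <- -1
  expect_identical(log_joint_interaction(trials, bad2, spec), -Inf)
})

test_that("near-noiseless data score ground truth above perturbed latents", {
  cohort <- make_cohort(1, sigma_x = 1e-4, seed = 33)
  cohort$sigma_t <- 1e-4
  trials <- run_phase(cohort[1, ], "feedback", seed = 34, n_trials = 40)
  spec <- quick_spec()
  truths <- condition_masses(cohort$condition[1])
  lat_true <- list(x_per = trials$x_per,
                   mass = truths[c("yellow-diamond", "red-dots")],
                   sigma_t = 1e-4, sigma_x = 1e-4)
  lat_off <- lat_true
  lat_off$mass <- lat_true$mass * 1.2
  expect_gt(log_joint_interaction(trials, lat_true, spec),
            log_joint_interaction(trials, lat_off, spec))
})

test_that("percept-marginal likelihood agrees with numerical integration", {
  trials <- feedback_trials(seed = 35, n_trials = 3)
  for (mc_ in c("newtonian", "linear")) {
    spec <- quick_spec(mc_)
    params <- list(sigma_t = 0.22, sigma_x = 0.07)
    pucks <- unique(as.character(trials$puck_id))
    if (mc_ == "newtonian") {
      params$mass <- setNames(rep(1.8, length(pucks)), pucks)
    } else {
      params$linear_factor <- setNames(rep(0.25, length(pucks)), pucks)
    }
    direct <- press_time_marginal_loglik(trials, params, spec)
    # brute-force: integrate each trial's percept on a fine grid
    numeric_ll <- sum(vapply(seq_len(nrow(trials)), function(i) {
      one <- trials[i, ]
      f <- function(xp) {
        lat <- params
        lat$x_per <- xp
        t_int <- if (mc_ == "newtonian") {
          ideal_press_time(xp, params$mass[as.character(one$puck_id)], spec$env)
        } else {
          params$linear_factor[as.character(one$puck_id)] * xp
        }
        dlnorm(one$t_pre, log(t_int) - params$sigma_t^2 / 2, params$sigma_t) *
          dlnorm(xp, log(one$x) + params$sigma_x^2, params$sigma_x)
      }
      log(integrate(f, 0, Inf, rel.tol = 1e-10)$value)
    }, numeric(1)))
    expect_equal(direct, numeric_ll, tolerance = 1e-6)
  }
})

test_that("MCMC posterior matches a grid-integration oracle on a single-mass model", {
  cohort <- make_cohort(1, seed = 36)
  trials <- run_phase(cohort[1, ], "no_feedback", seed = 37)
  spec <- interaction_spec("newtonian", "quadratic",
                           sigma_t_fixed = cohort$sigma_t[1],
                           sigma_x_fixed = 0.05,
                           chains = 2, warmup = 200, draws = 800, seed = 6)
  fit <- suppressWarnings(fit_interaction(trials, spec))
  post <- fit$draws$value[fit$draws$parameter == "mass[rings]"]
  # independent route: exact percept-marginal likelihood on a mass grid
  grid <- seq(0.5, 5, length.out = 2000)
  lw <- vapply(grid, function(m) {
    press_time_marginal_loglik(
      trials, list(mass = c(rings = m), sigma_t = cohort$sigma_t[1],
                   sigma_x = 0.05), spec
    ) + dgamma(m, 1, 0.5, log = TRUE)
  }, numeric(1))
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  expect_equal(mean(post), sum(grid * w), tolerance = 0.02)
  expect_equal(sd(post), sqrt(sum(grid^2 * w) - sum(grid * w)^2),
               tolerance = 0.15)
})

test_that("fits are reproducible and concentrate on truth as noise vanishes", {
  # a no-feedback phase has a constant generative belief (the geometric
  # mean of the two feedback-phase masses), so with vanishing noise the
  # posterior must concentrate exactly there
  cohort <- make_cohort(1, sigma_x = 0.002, seed = 38)
  cohort$sigma_t <- 0.005
  trials <- run_phase(cohort[1, ], "no_feedback", seed = 39, n_trials = 60)
  spec <- quick_spec(seed = 8)
  fit1 <- suppressWarnings(fit_interaction(trials, spec))
  fit2 <- suppressWarnings(fit_interaction(trials, spec))
  expect_identical(fit1$map, fit2$map)
  expect_identical(fit1$draws, fit2$draws)
  masses <- condition_masses(cohort$condition[1])
  belief <- exp(mean(log(masses[c("yellow-diamond", "red-dots")])))
  row <- tidy(fit1)[tidy(fit1)$parameter == "mass[rings]", ]
  expect_equal(row$estimate, belief, tolerance = 0.02)
  expect_lt(row$std.error, 0.05)
})

test_that("fit validates its inputs", {
  trials <- feedback_trials(seed = 40, n_trials = 8)
  expect_error(fit_interaction(trials[1, ], quick_spec()), "at least 2 trials")
  expect_error(fit_interaction(dplyr::select(trials, -"t_pre"), quick_spec()),
               "columns")
})

test_that("fix_nuisance pools sigma_x and keeps sigma_t per subject", {
  trials <- feedback_trials(n_subjects = 2, seed = 41, n_trials = 60)
  fit <- suppressWarnings(fit_interaction(trials, quick_spec(seed = 9)))
  nuis <- fix_nuisance(fit)
  expect_length(nuis$sigma_x, 1)
  expect_gt(nuis$sigma_x, 0)
  expect_equal(nrow(nuis$sigma_t), 2)
  one <- fix_nuisance(suppressWarnings(
    fit_interaction(trials[trials$subject_id == "s01", ], quick_spec(seed = 9))
  ))
  expect_equal(nrow(one$sigma_t), 1)
})

test_that("misspecified linear fits inflate the press-time variability", {
  trials <- feedback_trials("newtonian", seed = 43)
  fit_n <- suppressWarnings(fit_interaction(trials, quick_spec("newtonian", seed = 3)))
  fit_l <- suppressWarnings(fit_interaction(trials, quick_spec("linear", seed = 3)))
  st <- function(f) mean(f$draws$value[f$draws$parameter == "sigma_t"])
  expect_gt(st(fit_l), st(fit_n))
})

test_that("posterior predictive press-times are positive and track the data", {
  trials <- feedback_trials(seed = 44)
  fit_n <- suppressWarnings(fit_interaction(trials, quick_spec("newtonian", seed = 4)))
  fit_l <- suppressWarnings(fit_interaction(trials, quick_spec("linear", seed = 4)))
  pp_n <- posterior_predictive_press_times(fit_n, trials, n_draws = 20, seed = 5)
  pp_l <- posterior_predictive_press_times(fit_l, trials, n_draws = 20, seed = 5)
  expect_true(all(pp_n$t_pred > 0))
  expect_equal(nrow(pp_n), 20 * nrow(trials))
  ks_match <- ks_two_sample(trials$t_pre, pp_n$t_pred)$D
  ks_mismatch <- ks_two_sample(trials$t_pre, pp_l$t_pred)$D
  expect_lt(ks_match, ks_mismatch)
  expect_error(posterior_predictive_press_times(fit_n, trials, n_draws = 0),
               "at least 1")
})

test_that("residuals of a perfect prediction are flagged as degenerate", {
  trials <- feedback_trials(seed = 45, n_trials = 12)
  spec <- quick_spec()
  fake_map <- tibble::tibble(
    subject_id = trials$subject_id[1],
    parameter = c("mass[yellow-diamond]", "mass[red-dots]", "sigma_t",
                  "sigma_x", "lp"),
    value = c(1.5, 2.0, 0.2, 0.05, 0)
  )
  fake <- structure(list(map = fake_map, spec = spec), class = "interaction_fit")
  masses <- c("yellow-diamond" = 1.5, "red-dots" = 2.0)
  trials$t_pre <- ideal_press_time(trials$x,
                                   masses[as.character(trials$puck_id)])
  ra <- residual_analysis(fake, trials)
  expect_true(ra$degenerate)
  expect_equal(ra$rho, 0)
  expect_error(residual_analysis(fake, trials[1:2, ]), "at least 3")
})

test_that("matched fits leave little distance trend; misspecified fits do not", {
  trials <- feedback_trials("newtonian", n_subjects = 2, seed = 46)
  fit_n <- suppressWarnings(fit_interaction(trials, quick_spec("newtonian", seed = 12)))
  fit_l <- suppressWarnings(fit_interaction(trials, quick_spec("linear", seed = 12)))
  ra_n <- residual_analysis(fit_n, trials)
  ra_l <- residual_analysis(fit_l, trials)
  expect_lt(abs(ra_n$rho), 0.25)
  expect_lt(ra_l$rho, -0.3) # linear fit to square-root data: negative trend
  expect_gt(abs(ra_l$rho), abs(ra_n$rho))
})
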