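test_that("cohort generation splits conditions evenly and is reproducible", {
  cohort <- make_cohort(16, seed = 11)
  expect_equal(nrow(cohort), 16)
  expect_equal(sort(as.integer(table(cohort$condition))), c(8L, 8L))
  expect_identical(cohort, make_cohort(16, seed = 11))
  expect_false(identical(cohort, make_cohort(16, seed = 12)))
  expect_true(all(cohort$sigma_t >= 0.15 & cohort$sigma_t <= 0.33))
  expect_true(all(cohort$prior_mass_belief > 0))
  one <- make_cohort(1, seed = 2)
  expect_equal(nrow(one), 1)
  expect_true(one$condition %in% c("light-to-heavy", "heavy-to-light"))
})

test_that("distance percepts are positive with multiplicative (Weber-Fechner) spread", {
  set.seed(1)
  s2 <- perceive_distance(rep(2, 1e5), 0.1)
  s4 <- perceive_distance(rep(4, 1e5), 0.1)
  expect_true(all(s2 > 0))
  expect_equal(sd(s4) / sd(s2), 2, tolerance = 0.05)
  # mode anchored at the true distance: log-location is log(x) + sigma^2
  expect_equal(mean(log(s2)), log(2) + 0.1^2, tolerance = 0.005)
  expect_equal(perceive_distance(3, 0), 3)
  expect_error(perceive_distance(-1, 0.1), "positive")
})

test_that("intended press-times follow the class-specific scaling", {
  expect_equal(
    intended_press_time(4, "newtonian", mass_belief = 2) /
      intended_press_time(1, "newtonian", mass_belief = 2),
    2
  )
  expect_equal(
    intended_press_time(2, "linear", linear_factor = 0.3),
    2 * intended_press_time(1, "linear", linear_factor = 0.3)
  )
  expect_equal(
    intended_press_time(3, "newtonian", mass_belief = 2.0) /
      intended_press_time(3, "newtonian", mass_belief = 1.5),
    4 / 3
  )
})

test_that("emitted press-times place the cost-optimal statistic at the intent", {
  set.seed(2)
  t_int <- 0.8
  sig <- 0.3
  # quadratic loss targets the mean
  expect_equal(mean(emit_press_time(rep(t_int, 1e6), sig, "quadratic")),
               t_int, tolerance = 0.005)
  # absolute loss targets the median
  expect_equal(median(emit_press_time(rep(t_int, 1e6), sig, "absolute")),
               t_int, tolerance = 0.005)
  # 0-1 loss targets the mode: log-location must be log(t_int) + sigma^2
  z <- emit_press_time(rep(t_int, 1e5), sig, "zero_one")
  expect_equal(mean(log(z)), log(t_int) + sig^2, tolerance = 0.01)
  expect_equal(emit_press_time(0.5, 0, "quadratic"), 0.5)
  expect_error(emit_press_time(-1, 0.2), "positive")
})

test_that("phase structure matches the design: counts, pucks, alternation, ranges", {
  cohort <- make_cohort(1, seed = 5)
  pr <- run_phase(cohort[1, ], "prior", seed = 1)
  expect_equal(nrow(pr), 50)
  expect_equal(unique(pr$puck_id), "black")
  expect_false(any(pr$feedback_shown))
  expect_true(all(is.na(pr$error)))

  fb <- run_phase(cohort[1, ], "feedback", seed = 2)
  expect_equal(nrow(fb), 200)
  expect_true(all(fb$feedback_shown))
  # blocks of four, alternating two pucks
  blocks <- split(fb$puck_id, (fb$trial_index - 1) %/% 4)
  expect_true(all(vapply(blocks, function(b) length(unique(b)) == 1, logical(1))))
  expect_equal(unique(fb$puck_id[1:4]), "yellow-diamond")
  expect_equal(unique(fb$puck_id[5:8]), "red-dots")

  nf <- run_phase(cohort[1, ], "no_feedback", seed = 3)
  expect_equal(nrow(nf), 100)
  expect_equal(unique(nf$puck_id), "rings")

  all_ph <- dplyr::bind_rows(pr, fb, nf)
  expect_true(all(all_ph$x >= 1 & all_ph$x <= 5))
  expect_true(all(all_ph$t_pre > 0))
  # determinism
  expect_identical(fb, run_phase(cohort[1, ], "feedback", seed = 2))
})

test_that("feedback-phase learning drives mass beliefs towards the truth", {
  cohort <- make_cohort(1, seed = 9)
  fb <- run_phase(cohort[1, ], "feedback", seed = 4)
  truths <- condition_masses(cohort$condition[1])
  final <- attr(fb, "belief")
  expect_equal(exp(final[["yellow-diamond"]]$log_value),
               truths[["yellow-diamond"]], tolerance = 0.05)
  expect_equal(exp(final[["red-dots"]]$log_value),
               truths[["red-dots"]], tolerance = 0.05)
})

test_that("press-time spread grows with distance in generated data (Weber-Fechner)", {
  trials <- feedback_trials(n_subjects = 4, seed = 21)
  bins <- cut(trials$x, c(1, 2.33, 3.66, 5), include.lowest = TRUE)
  sds <- tapply(trials$t_pre, bins, sd)
  expect_true(all(diff(sds) > 0))
})

test_that("collision movies have the canonical structure and exact dynamics", {
  ev <- generate_collisions(2.5, c("yellow-diamond" = 1.5, "red-dots" = 2.0),
                            seed = 3)
  expect_equal(nrow(ev), 24)
  expect_equal(as.integer(table(ev$known_puck_id)), c(12L, 12L))
  # conservation, exactly
  p_pre <- ev$mF * ev$vF + ev$mNF_true * ev$vNF
  p_post <- ev$mF * ev$uF + ev$mNF_true * ev$uNF
  expect_equal(p_pre, p_post, tolerance = 1e-12)
  e_pre <- ev$mF * ev$vF^2 + ev$mNF_true * ev$vNF^2
  e_post <- ev$mF * ev$uF^2 + ev$mNF_true * ev$uNF^2
  expect_equal(e_pre, e_post, tolerance = 1e-12)
  # all velocities positive (required by the log-normal percepts)
  expect_true(all(ev$vF > 0 & ev$vNF > 0 & ev$uF > 0 & ev$uNF > 0))
  expect_identical(ev, generate_collisions(
    2.5, c("yellow-diamond" = 1.5, "red-dots" = 2.0), seed = 3
  ))
  expect_error(generate_collisions(2.5, c(a = 1.5), seed = 1), "length 2")
})
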