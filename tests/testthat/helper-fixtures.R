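# Shared fixture builders; everything is generated in code under fixed seeds.

small_env <- function() env_params()

# one-subject feedback-phase dataset under a chosen generative model
feedback_trials <- function(model_class = "newtonian",
                            cost_function = "quadratic",
                            n_subjects = 1, seed = 42, n_trials = NULL) {
  cohort <- make_cohort(n_subjects, model_class = model_class,
                        cost_function = cost_function, seed = seed)
  purrr::map_dfr(seq_len(n_subjects), function(j) {
    run_phase(cohort[j, ], "feedback", env = small_env(),
              seed = seed + 100 + j, n_trials = n_trials)
  })
}

quick_spec <- function(model_class = "newtonian",
                       cost_function = "quadratic", ...) {
  interaction_spec(model_class, cost_function,
                   chains = 2, warmup = 150, draws = 250, ...)
}

# brute-force two-sample KS statistic: max gap between empirical CDFs
ks_oracle <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- vapply(grid, function(g) mean(a <= g), numeric(1))
  Fb <- vapply(grid, function(g) mean(b <= g), numeric(1))
  max(abs(Fa - Fb))
}

# elastic-collision oracle: solve the two conservation equations with
# polyroot and pick the non-trivial root
collision_oracle <- function(vF, vNF, mF, mNF) {
  p <- mF * vF + mNF * vNF
  E2 <- mF * vF^2 + mNF * vNF^2
  # substitute uF = (p - mNF*uNF)/mF into the energy equation:
  # (p - mNF uNF)^2 / mF + mNF uNF^2 = E2
  a2 <- mNF^2 / mF + mNF
  a1 <- -2 * p * mNF / mF
  a0 <- p^2 / mF - E2
  roots <- Re(polyroot(c(a0, a1, a2)))
  uNF <- roots[which.max(abs(roots - vNF))] # non-trivial solution
  list(uF = (p - mNF * uNF) / mF, uNF = uNF)
}
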