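# Trial-level generative simulation of the four experimental phases and the
# collision movies.

PHASES <- c("prior", "feedback", "no_feedback", "collisions_no_feedback")

#' Simulate one experimental phase for one subject
#'
#' Generates the trial table of a single phase from a participant profile
#' (one row of [make_cohort()]). Initial distances are i.i.d. uniform on the
#' environment's `distance_range`. Each trial runs the full generative path:
#' the subject perceives the distance ([perceive_distance()]), forms an
#' intended press-time from its model class and current belief
#' ([intended_press_time()]), and emits a motor-noisy press-time
#' ([emit_press_time()]). When motion is simulated (all phases but the
#' prior phase, where the screen is blanked before release) the resulting
#' slide is integrated with [simulate_slide()] and the signed final-position
#' error recorded.
#'
#' Phase structure: `prior` is 50 trials with a single unknown puck and no
#' feedback; `feedback` is 200 trials alternating two pucks in blocks of
#' four with visual feedback, during which the subject updates its belief
#' trial-by-trial via `learning_rule`; `no_feedback` and
#' `collisions_no_feedback` are 100 trials each with the unknown puck and no
#' feedback. Beliefs for the no-feedback phase default to the (geometric)
#' mean of the two feedback-phase beliefs; after watching the collisions the
#' belief moves a configurable fraction (`transfer_weight`, log scale)
#' towards the true mass of the unknown puck.
#'
#' @param profile One-row tibble (or named list) with at least
#'   `subject_id`, `condition`, `model_class`, `cost_function`, `sigma_t`,
#'   `sigma_x`, `prior_mass_belief`, `linear_factor`.
#' @param phase One of `"prior"`, `"feedback"`, `"no_feedback"`,
#'   `"collisions_no_feedback"`.
#' @param env An [env_params()] object.
#' @param true_masses Named masses (kg) of the pucks actually simulated;
#'   defaults to [condition_masses()] of the profile's condition.
#' @param seed Integer seed for this phase.
#' @param n_trials Number of trials; defaults to the phase's canonical count
#'   (50 / 200 / 100 / 100).
#' @param learning_rule Function `(state, implied_value)` returning an
#'   updated state `list(log_value, weight)`; used in the feedback phase.
#'   Default [running_belief_update()].
#' @param prior_weight Pseudo-observation weight of the initial belief in
#'   the feedback-phase update (default 2: beliefs stabilise within a few
#'   trials, with two pucks on the six-trial scale).
#' @param transfer_weight Log-scale weight on the true unknown-puck mass
#'   when forming the post-collision belief (default 0.7: transfer is
#'   substantial but imperfect).
#' @param carry_belief Optional named list of belief state carried in from
#'   earlier phases (as returned in the `belief` attribute); when `NULL`
#'   the earlier phases are implied by the profile's deterministic rules.
#' @return A tibble with one row per trial: `subject_id`, `condition`,
#'   `phase`, `trial_index`, `puck_id`, `x`, `x_per` (latent),
#'   `mass_belief` (latent; linear-class subjects report their slope
#'   instead), `t_int` (latent), `t_pre`, `error`, `feedback_shown`. The
#'   final belief state is attached as attribute `"belief"`.
#' @export
run_phase <- function(profile, phase, env = env_params(),
                      true_masses = NULL, seed = 1L, n_trials = NULL,
                      learning_rule = running_belief_update,
                      prior_weight = 2, transfer_weight = 0.7,
                      carry_belief = NULL) {
  profile <- as.list(profile)
  phase <- match.arg(phase, PHASES)
  if (is.null(true_masses)) true_masses <- condition_masses(profile$condition)
  n_default <- c(prior = 50L, feedback = 200L, no_feedback = 100L,
                 collisions_no_feedback = 100L)
  if (is.null(n_trials)) n_trials <- n_default[[phase]]
  linear <- identical(match_model_class(profile$model_class), "linear")

  pucks <- switch(phase,
    prior = rep("black", n_trials),
    feedback = rep_len(rep(c("yellow-diamond", "red-dots"), each = 4L), n_trials),
    rep("rings", n_trials)
  )

  belief <- phase_entry_belief(profile, phase, true_masses,
                               transfer_weight, prior_weight, carry_belief, env)

  withr_seed(seed, {
    x <- stats::runif(n_trials, env$distance_range[1], env$distance_range[2])
    rec <- vector("list", n_trials)
    for (i in seq_len(n_trials)) {
      pk <- pucks[i]
      b <- belief[[pk]]
      value <- exp(b$log_value)
      x_per <- perceive_distance(x[i], profile$sigma_x, n = 1)
      t_int <- if (linear) {
        intended_press_time(x_per, "linear", linear_factor = value, env = env)
      } else {
        intended_press_time(x_per, "newtonian", mass_belief = value, env = env)
      }
      t_pre <- emit_press_time(t_int, profile$sigma_t, profile$cost_function, n = 1)
      err <- NA_real_
      if (phase != "prior") {
        m_true <- true_masses[[pk]]
        d <- simulate_slide(release_velocity(t_pre, m_true, env), env)$displacement
        err <- d - x[i]
        if (phase == "feedback") {
          # subject reads off the slid distance (with perceptual noise) and
          # inverts its own model to an implied mass / slope
          d_obs <- perceive_distance(d, profile$sigma_x, n = 1)
          implied <- if (linear) {
            t_pre / d_obs
          } else {
            env$interaction_force * t_pre /
              sqrt(2 * env$friction_coefficient * env$gravity * d_obs)
          }
          belief[[pk]] <- learning_rule(b, implied)
        }
      }
      rec[[i]] <- list(x_per = x_per, mass_belief = value,
                       t_int = t_int, t_pre = t_pre, error = err)
    }
    out <- tibble::tibble(
      subject_id = profile$subject_id,
      condition = profile$condition,
      phase = phase,
      trial_index = seq_len(n_trials),
      puck_id = pucks,
      x = x,
      x_per = vapply(rec, `[[`, numeric(1), "x_per"),
      mass_belief = vapply(rec, `[[`, numeric(1), "mass_belief"),
      t_int = vapply(rec, `[[`, numeric(1), "t_int"),
      t_pre = vapply(rec, `[[`, numeric(1), "t_pre"),
      error = vapply(rec, `[[`, numeric(1), "error"),
      feedback_shown = phase == "feedback"
    )
    attr(out, "belief") <- belief
    out
  })
}

# Belief state at phase entry, replaying the deterministic between-phase rules.
phase_entry_belief <- function(profile, phase, true_masses,
                               transfer_weight, prior_weight, carry = NULL,
                               env = env_params()) {
  linear <- identical(match_model_class(profile$model_class), "linear")
  base_value <- if (linear) profile$linear_factor else profile$prior_mass_belief
  fresh <- function(v) list(log_value = log(v), weight = prior_weight)
  if (!is.null(carry)) return(carry)
  if (phase %in% c("prior", "feedback")) {
    pucks <- if (phase == "prior") "black" else c("yellow-diamond", "red-dots")
    return(stats::setNames(lapply(pucks, function(p) fresh(base_value)), pucks))
  }
  # phases 3/4 presume converged feedback-phase beliefs: the generative
  # learning rule converges to the true masses (slopes), so the carried
  # belief is their geometric mean
  conv <- if (linear) {
    # slope that lands each feedback puck on target at mid-range
    vapply(c("yellow-diamond", "red-dots"),
           function(p) ideal_press_time(3, true_masses[[p]], env) / 3, numeric(1))
  } else {
    c(true_masses[["yellow-diamond"]], true_masses[["red-dots"]])
  }
  log_mix <- mean(log(conv))
  if (phase == "collisions_no_feedback") {
    log_target <- if (linear) {
      log(ideal_press_time(3, true_masses[["rings"]], env) / 3)
    } else {
      log(true_masses[["rings"]])
    }
    log_mix <- transfer_weight * log_target + (1 - transfer_weight) * log_mix
  }
  list(rings = list(log_value = log_mix, weight = prior_weight))
}

#' Running precision-weighted belief update
#'
#' Conjugate-style running update of a log-scale belief: the new log-belief
#' is the weight-averaged combination of the previous log-belief and the
#' newly implied value, and the weight (pseudo-observation count) increments
#' by one. With the default prior weight of 2, beliefs effectively converge
#' within a handful of feedback trials.
#'
#' @param state List with `log_value` and `weight`.
#' @param implied Newly implied value (mass in kg, or slope in s/m) from one
#'   feedback trial.
#' @return Updated state list.
#' @export
running_belief_update <- function(state, implied) {
  w <- state$weight
  list(log_value = (w * state$log_value + log(implied)) / (w + 1),
       weight = w + 1)
}

#' Simulate a full cohort across all four phases
#'
#' Runs [run_phase()] for every subject and phase and
#' [generate_collisions()] for every subject, deriving per-subject,
#' per-phase RNG substreams from the single cohort seed.
#'
#' @param cohort A cohort tibble from [make_cohort()].
#' @param env An [env_params()] object.
#' @param seed Integer master seed.
#' @param phases Character vector of phases to simulate.
#' @param ... Passed on to [run_phase()].
#' @return A list with `trials` (row-bound trial tibble including latent
#'   sidecar columns) and `collisions` (per-subject collision events).
#' @examples
#' \donttest{
#' cohort <- make_cohort(2, seed = 1)
#' dat <- simulate_cohort(cohort, seed = 1)
#' dplyr::count(dat$trials, phase)
#' }
#' @export
simulate_cohort <- function(cohort, env = env_params(), seed = 1L,
                            phases = PHASES, ...) {
  trials <- purrr::map_dfr(seq_len(nrow(cohort)), function(j) {
    profile <- cohort[j, ]
    purrr::map_dfr(phases, function(ph) {
      run_phase(profile, ph, env = env,
                seed = derive_seed(seed, paste0(profile$subject_id, ph)), ...)
    })
  })
  collisions <- purrr::map_dfr(seq_len(nrow(cohort)), function(j) {
    profile <- cohort[j, ]
    masses <- condition_masses(profile$condition)
    ev <- generate_collisions(
      mNF_true = masses[["rings"]],
      known_pucks = masses[c("yellow-diamond", "red-dots")],
      env = env,
      seed = derive_seed(seed, paste0(profile$subject_id, "coll"))
    )
    dplyr::mutate(ev,
                  subject_id = profile$subject_id,
                  condition = profile$condition,
                  .before = 1)
  })
  list(trials = trials, collisions = collisions)
}

#' Generate a movie of elastic collisions with an unknown puck
#'
#' Emits `n_collisions` one-dimensional elastic collisions between the
#' unknown puck and the two known pucks (half with each, in randomised
#' order). The rear known puck slides in at a speed drawn uniformly from
#' `vF_range` and catches the slower unknown puck (speed from `vNF_range`,
#' same direction), so all pre- and post-collision velocities are strictly
#' positive — as required by the log-normal velocity percepts of the
#' observation model. Post-collision velocities are exact elastic solutions
#' ([elastic_collision()]); collisions are frictionless.
#'
#' @param mNF_true True mass (kg) of the unknown puck.
#' @param known_pucks Named numeric of length 2: masses of the known pucks.
#' @param env An [env_params()] object (unused by the collision dynamics
#'   themselves, kept for interface symmetry).
#' @param seed Integer seed.
#' @param n_collisions Total number of collisions (split evenly; default 24,
#'   i.e. 12 with each known puck).
#' @param vF_range,vNF_range Uniform speed ranges (m/s) of the known and
#'   unknown puck.
#' @return A tibble with `event_index`, `known_puck_id`, `vF`, `vNF`,
#'   `uF`, `uNF`, `mF` and the ground-truth sidecar column `mNF_true`.
#' @export
generate_collisions <- function(mNF_true, known_pucks, env = env_params(),
                                seed = 1L, n_collisions = 24L,
                                vF_range = c(1.5, 2.5),
                                vNF_range = c(0.6, 1.2)) {
  if (length(known_pucks) != 2 || is.null(names(known_pucks))) {
    stop("`known_pucks` must be a named numeric vector of length 2", call. = FALSE)
  }
  stopifnot(mNF_true > 0, all(known_pucks > 0), n_collisions >= 2)
  half <- n_collisions %/% 2L
  withr_seed(seed, {
    ids <- sample(rep(names(known_pucks), c(half, n_collisions - half)))
    vF <- stats::runif(n_collisions, vF_range[1], vF_range[2])
    vNF <- stats::runif(n_collisions, vNF_range[1], vNF_range[2])
    mF <- unname(known_pucks[ids])
    u <- elastic_collision(vF, vNF, mF, mNF_true)
    tibble::tibble(
      event_index = seq_len(n_collisions),
      known_puck_id = ids,
      vF = vF, vNF = vNF, uF = u$uF, uNF = u$uNF,
      mF = mF, mNF_true = mNF_true
    )
  })
}
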