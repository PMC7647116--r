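# Synthetic participants: generative profiles and the log-normal perception,
# decision and motor-noise primitives they act with.

#' Condition-specific true puck masses
#'
#' The two between-subject conditions differ in the pair of puck masses used
#' in the feedback phase and in the mass of the unknown puck of the later
#' phases: "light-to-heavy" slides 1.5 and 2.0 kg pucks with an unknown
#' 2.5 kg puck, "heavy-to-light" slides 2.0 and 2.5 kg pucks with an unknown
#' 1.5 kg puck.
#'
#' @param condition `"light-to-heavy"` or `"heavy-to-light"`.
#' @return Named numeric vector of masses (kg) for pucks
#'   `yellow-diamond`, `red-dots` (feedback phase) and `rings` (unknown).
#' @export
condition_masses <- function(condition = c("light-to-heavy", "heavy-to-light")) {
  condition <- match.arg(condition)
  if (condition == "light-to-heavy") {
    c("yellow-diamond" = 1.5, "red-dots" = 2.0, "rings" = 2.5)
  } else {
    c("yellow-diamond" = 2.0, "red-dots" = 2.5, "rings" = 1.5)
  }
}

#' Generate a cohort of synthetic participant profiles
#'
#' Each profile holds a subject's true generative parameters: which press-time
#' rule it uses (`newtonian`: press-time proportional to mass times the
#' square-root of perceived distance; `linear`: proportional to perceived
#' distance), which cost function shapes its motor output, its perceptual and
#' press-time log-scale noise, and its initial mass belief. Half the cohort is
#' assigned to each condition (first half light-to-heavy, by subject order,
#' with assignment randomised through the profile seed chain).
#'
#' Defaults emulate the study conditions: 16 subjects, perceptual log-SD
#' `sigma_x = 0.05`, per-subject press-time log-SD drawn uniformly from
#' `[0.15, 0.33]`, a prior-phase mass belief drawn from a gamma with mean
#' 2 kg and SD 0.6 kg, newtonian model class and quadratic cost throughout.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param model_class `"newtonian"` or `"linear"`; recycled across subjects.
#' @param cost_function `"zero_one"`, `"absolute"` or `"quadratic"`; recycled.
#' @param sigma_x Perceptual log-scale SD (> 0).
#' @param sigma_t_range Range the per-subject press-time log-scale SD is
#'   drawn from (uniform).
#' @param prior_belief_mean,prior_belief_sd Mean and SD (kg) of the gamma
#'   distribution the prior-phase mass belief is drawn from.
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @return A tibble with one row per subject: `subject_id`, `condition`,
#'   `model_class`, `cost_function`, `sigma_t`, `sigma_x`,
#'   `prior_mass_belief`, `linear_factor`, `rng_seed`.
#' @examples
#' make_cohort(4, seed = 1)
#' @export
make_cohort <- function(n_subjects = 16,
                        model_class = "newtonian",
                        cost_function = "quadratic",
                        sigma_x = 0.05,
                        sigma_t_range = c(0.15, 0.33),
                        prior_belief_mean = 2,
                        prior_belief_sd = 0.6,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, sigma_x > 0,
            length(sigma_t_range) == 2, all(sigma_t_range > 0),
            prior_belief_mean > 0, prior_belief_sd > 0)
  model_class <- match_model_class(model_class)
  cost_function <- match_cost_function(cost_function)
  withr_seed(seed, {
    n_l2h <- ceiling(n_subjects / 2)
    condition <- sample(rep(
      c("light-to-heavy", "heavy-to-light"),
      c(n_l2h, n_subjects - n_l2h)
    ))
    sigma_t <- stats::runif(n_subjects, sigma_t_range[1], sigma_t_range[2])
    shape <- (prior_belief_mean / prior_belief_sd)^2
    rate <- prior_belief_mean / prior_belief_sd^2
    prior_belief <- stats::rgamma(n_subjects, shape = shape, rate = rate)
    tibble::tibble(
      subject_id = sprintf("s%02d", seq_len(n_subjects)),
      condition = condition,
      model_class = rep_len(model_class, n_subjects),
      cost_function = rep_len(cost_function, n_subjects),
      sigma_t = sigma_t,
      sigma_x = sigma_x,
      prior_mass_belief = prior_belief,
      # heuristic slope chosen so the linear rule agrees with the ideal
      # press-time at mid-range (3 m) for the subject's prior belief
      linear_factor = ideal_press_time(3, prior_belief) / 3,
      rng_seed = sample.int(2^30, n_subjects)
    )
  })
}

#' Sample a perceived distance with Weber-Fechner scaling
#'
#' Perception of the puck-to-target distance is modelled as log-normal with
#' constant log-scale SD `sigma_x`, so the SD of the percept grows in
#' proportion to the distance (Weber-Fechner scaling) and samples are
#' strictly positive. The mode of the percept distribution is anchored at
#' the true distance (log-location `log(x) + sigma_x^2`), mirroring the
#' velocity percepts of the observation model.
#'
#' @param x True distance(s), metres (> 0).
#' @param sigma_x Perceptual log-scale SD (> 0; `0` returns `x` exactly).
#' @param n Number of samples per element of `x` (default 1, vectorised
#'   over `x`).
#' @return Perceived distance(s), metres.
#' @export
perceive_distance <- function(x, sigma_x, n = length(x)) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("`x` must be finite and strictly positive", call. = FALSE)
  }
  if (sigma_x < 0) stop("`sigma_x` must be non-negative", call. = FALSE)
  if (sigma_x == 0) return(rep_len(x, n))
  stats::rlnorm(n, meanlog = log(x) + sigma_x^2, sdlog = sigma_x)
}

#' Intended press-time under a model class
#'
#' The deterministic press-time a subject aims for given its percept of the
#' distance: the ideal Newtonian press-time at the believed mass for the
#' `newtonian` class, or `linear_factor * x_per` for the `linear` heuristic.
#'
#' @param x_per Perceived distance(s), metres (> 0).
#' @param model_class `"newtonian"` or `"linear"`.
#' @param mass_belief Believed mass, kg (newtonian class).
#' @param linear_factor Heuristic slope, s/m (linear class).
#' @param env An [env_params()] object.
#' @return Intended press-time(s), seconds.
#' @export
intended_press_time <- function(x_per, model_class, mass_belief = NULL,
                                linear_factor = NULL, env = env_params()) {
  if (any(!is.finite(x_per)) || any(x_per <= 0)) {
    stop("`x_per` must be finite and strictly positive", call. = FALSE)
  }
  model_class <- match_model_class(model_class)
  if (model_class == "newtonian") {
    if (is.null(mass_belief)) stop("`mass_belief` required for the newtonian class")
    ideal_press_time(x_per, mass_belief, env)
  } else {
    if (is.null(linear_factor) || linear_factor <= 0) {
      stop("positive `linear_factor` required for the linear class")
    }
    linear_factor * x_per
  }
}

#' Cost-function shift of the press-time log-location
#'
#' For a log-normal press-time distribution with log-scale `sigma_t`, the
#' statistic a subject can place at its intended press-time depends on its
#' cost function: the 0-1 loss is minimised by the mode
#' `exp(mu - sigma^2)`, the absolute loss by the median `exp(mu)` and the
#' quadratic loss by the mean `exp(mu + sigma^2 / 2)`. Solving each for the
#' log-location `mu` with the statistic pinned at `t_int` gives the additive
#' shift returned here: `+sigma_t^2` (0-1), `0` (absolute),
#' `-sigma_t^2 / 2` (quadratic), so that
#' `mu = log(t_int) + cost_shift(cost, sigma_t)`.
#'
#' @param cost_function `"zero_one"`, `"absolute"` or `"quadratic"`.
#' @param sigma_t Press-time log-scale SD.
#' @return Additive shift of the log-location.
#' @export
cost_shift <- function(cost_function, sigma_t) {
  cost_function <- match_cost_function(cost_function)
  switch(cost_function,
    zero_one = sigma_t^2,
    absolute = 0 * sigma_t,
    quadratic = -sigma_t^2 / 2
  )
}

#' Emit a motor-noisy press-time
#'
#' Samples the actually produced press-time from a log-normal with log-scale
#' `sigma_t`, its log-location chosen (via [cost_shift()]) so that the
#' cost-optimal statistic of the emitted distribution equals the intended
#' press-time: mode for the 0-1 loss, median for the absolute loss, mean for
#' the quadratic loss.
#'
#' @param t_int Intended press-time(s), seconds (> 0).
#' @param sigma_t Press-time log-scale SD (> 0; `0` returns `t_int`).
#' @param cost_function `"zero_one"`, `"absolute"` or `"quadratic"`.
#' @param n Number of samples (default vectorised over `t_int`).
#' @return Emitted press-time(s), seconds; always positive.
#' @export
emit_press_time <- function(t_int, sigma_t, cost_function = "quadratic",
                            n = length(t_int)) {
  if (any(!is.finite(t_int)) || any(t_int <= 0)) {
    stop("`t_int` must be finite and strictly positive", call. = FALSE)
  }
  if (sigma_t < 0) stop("`sigma_t` must be non-negative", call. = FALSE)
  if (sigma_t == 0) return(rep_len(t_int, n))
  mu <- log(t_int) + cost_shift(cost_function, sigma_t)
  stats::rlnorm(n, meanlog = mu, sdlog = sigma_t)
}

# ---- internal helpers -------------------------------------------------------

match_model_class <- function(x) {
  match.arg(x, c("newtonian", "linear"), several.ok = FALSE)
}

match_cost_function <- function(x) {
  match.arg(x, c("zero_one", "absolute", "quadratic"), several.ok = FALSE)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Deterministic substream seed derived from a parent seed and a label.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  (as.integer(seed) + 7919L * (h %% 100000L)) %% 2147483647L
}
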