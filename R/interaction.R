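# Hierarchical Bayesian interaction model: inference over latent mass
# beliefs, percepts and variabilities from observed press-times.

#' Specification of the interaction model
#'
#' Describes the generative model fitted to press-time data: the joint
#' density factorises as
#' `p(x) p(sigma_x) p(x_per | x, sigma_x) p(m) p(sigma_t)
#'  p(t_pre | x_per, m, sigma_t, theta)`,
#' where the percept `x_per` is log-normal around the true distance
#' (Weber-Fechner scaling), the intended press-time is either the Newtonian
#' press-time at the believed mass or a linear function of the percept, and
#' the observed press-time is log-normal around the intended time with the
#' cost-function shift of [cost_shift()]. Priors on the mass, press-time
#' variability and perceptual variability are gamma distributions
#' (positive support); the defaults are weakly informative (mass: mean 2 kg,
#' SD 2 kg; `sigma_t`: mean 0.25, SD 0.25 log-units; `sigma_x`: mean 0.1,
#' SD 0.1; linear slope: mean 0.5, SD 0.5 s/m).
#'
#' @param model_class `"newtonian"` or `"linear"`.
#' @param cost_function `"zero_one"`, `"absolute"` or `"quadratic"`.
#' @param priors Named list of `c(shape, rate)` gamma hyperparameters for
#'   `mass`, `sigma_t`, `sigma_x`, `linear_factor`; partial lists are
#'   merged with the defaults.
#' @param sigma_x_fixed,sigma_t_fixed Optional fixed values; when supplied
#'   the parameter is not sampled (used for the phases analysed with the
#'   nuisance parameters pinned at their feedback-phase estimates).
#' @param env An [env_params()] object.
#' @param chains,warmup,draws MCMC settings (per chain).
#' @param seed Integer MCMC seed.
#' @return An object of class `interaction_spec`.
#' @export
interaction_spec <- function(model_class = "newtonian",
                             cost_function = "quadratic",
                             priors = list(),
                             sigma_x_fixed = NULL,
                             sigma_t_fixed = NULL,
                             env = env_params(),
                             chains = 2L, warmup = 400L, draws = 1000L,
                             seed = 1L) {
  default_priors <- list(
    mass = c(shape = 1, rate = 0.5),
    sigma_t = c(shape = 1, rate = 4),
    # centred on a 5% Weber fraction for visual distance estimation;
    # sigma_x is only weakly identified by press-times (it enters the
    # marginal variance as sigma_x^2/4 against sigma_t^2), so the prior
    # carries the scale
    sigma_x = c(shape = 2, rate = 40),
    linear_factor = c(shape = 1, rate = 2)
  )
  priors <- utils::modifyList(default_priors, priors)
  lapply(priors, function(p) stopifnot(all(p > 0)))
  stopifnot(chains >= 1, warmup >= 0, draws >= 1)
  structure(
    list(
      model_class = match_model_class(model_class),
      cost_function = match_cost_function(cost_function),
      priors = priors,
      sigma_x_fixed = sigma_x_fixed,
      sigma_t_fixed = sigma_t_fixed,
      env = env,
      mcmc = list(chains = as.integer(chains), warmup = as.integer(warmup),
                  draws = as.integer(draws), seed = as.integer(seed))
    ),
    class = "interaction_spec"
  )
}

# log of the deterministic press-time multiplier: log t_int = base + b * log x_per
model_base <- function(spec, log_param) {
  if (spec$model_class == "newtonian") {
    env <- spec$env
    list(base = log_param - log(env$interaction_force) +
           0.5 * log(2 * env$friction_coefficient * env$gravity),
         b = 0.5)
  } else {
    list(base = log_param, b = 1)
  }
}

#' Log joint density of the interaction model
#'
#' Evaluates the unnormalised log joint of observed data and latent values
#' under an [interaction_spec()]: the sum of the log-normal percept terms,
#' the log-normal press-time likelihood (with the cost-function shift of the
#' spec), and the gamma log-priors on the mass (or slope), `sigma_t` and
#' `sigma_x`. Values outside the support return `-Inf` rather than raising.
#'
#' @param trials Tibble with columns `x`, `t_pre`, `puck_id` (single
#'   subject).
#' @param latents Named list: `x_per` (length `nrow(trials)`), `mass`
#'   (named by puck, newtonian class) or `linear_factor` (named by puck),
#'   `sigma_t`, `sigma_x`.
#' @param spec An [interaction_spec()].
#' @return Scalar log density.
#' @export
log_joint_interaction <- function(trials, latents, spec) {
  stopifnot(inherits(spec, "interaction_spec"))
  if (any(trials$x <= 0) || any(trials$t_pre <= 0)) {
    stop("trials must have positive `x` and `t_pre`", call. = FALSE)
  }
  x_per <- latents$x_per
  sigma_t <- latents$sigma_t
  sigma_x <- latents$sigma_x
  pars <- if (spec$model_class == "newtonian") latents$mass else latents$linear_factor
  if (length(x_per) != nrow(trials)) {
    stop("`x_per` must have one value per trial", call. = FALSE)
  }
  if (any(x_per <= 0) || sigma_t <= 0 || sigma_x <= 0 || any(pars <= 0)) {
    return(-Inf)
  }
  k <- as.character(trials$puck_id)
  if (!all(k %in% names(pars))) {
    stop("latent mass/slope missing for some pucks", call. = FALSE)
  }
  mb <- model_base(spec, log(pars[k]))
  meanlog <- mb$base + mb$b * log(x_per) + cost_shift(spec$cost_function, sigma_t)
  lp <- sum(stats::dlnorm(trials$t_pre, meanlog, sigma_t, log = TRUE)) +
    sum(stats::dlnorm(x_per, log(trials$x) + sigma_x^2, sigma_x, log = TRUE))
  pr <- spec$priors
  par_prior <- if (spec$model_class == "newtonian") pr$mass else pr$linear_factor
  lp <- lp + sum(stats::dgamma(pars, par_prior[1], par_prior[2], log = TRUE))
  if (is.null(spec$sigma_t_fixed)) {
    lp <- lp + stats::dgamma(sigma_t, pr$sigma_t[1], pr$sigma_t[2], log = TRUE)
  }
  if (is.null(spec$sigma_x_fixed)) {
    lp <- lp + stats::dgamma(sigma_x, pr$sigma_x[1], pr$sigma_x[2], log = TRUE)
  }
  lp
}

#' Marginal log-likelihood of press-times with the percept integrated out
#'
#' Because the log-percept is Gaussian and enters the log press-time
#' linearly, the per-trial percept can be integrated analytically: under the
#' newtonian class `log t_pre ~ N(base + (log x + sigma_x^2)/2 + shift,
#' sigma_t^2 + sigma_x^2/4)` and under the linear class the percept enters
#' with coefficient 1. This closed form is used by the product-space sampler
#' and serves as an independent cross-check of the latent-sampling fit.
#'
#' @inheritParams log_joint_interaction
#' @param params Named list: `mass` or `linear_factor` (named by puck),
#'   `sigma_t`, `sigma_x`.
#' @return Scalar log-likelihood (no prior terms).
#' @export
press_time_marginal_loglik <- function(trials, params, spec) {
  pars <- if (spec$model_class == "newtonian") params$mass else params$linear_factor
  sigma_t <- params$sigma_t
  sigma_x <- params$sigma_x
  if (any(pars <= 0) || sigma_t <= 0 || sigma_x < 0) return(-Inf)
  k <- as.character(trials$puck_id)
  mb <- model_base(spec, log(pars[k]))
  meanlog <- mb$base + mb$b * (log(trials$x) + sigma_x^2) +
    cost_shift(spec$cost_function, sigma_t)
  sdlog <- sqrt(sigma_t^2 + mb$b^2 * sigma_x^2)
  sum(stats::dlnorm(trials$t_pre, meanlog, sdlog, log = TRUE))
}

#' Fit the interaction model by MCMC
#'
#' Runs an adaptive Metropolis-within-Gibbs sampler independently for each
#' subject in `trials`: the per-trial log-percepts are updated with exact
#' Gibbs draws (their full conditional is Gaussian), and the mass (or
#' slope), `sigma_t` and `sigma_x` with adaptive random-walk steps on the
#' log scale against the exact percept-marginalised posterior (a collapsed
#' Gibbs scheme: the sampled joint is unchanged but the parameters mix
#' freely). The MAP is the retained draw with the highest marginal log
#' posterior of the parameters (the joint density including the per-trial
#' latents is unbounded in the small-`sigma_x` limit and would make a
#' highest-joint-draw MAP degenerate). Convergence is
#' summarised with split-chain R-hat and effective sample size; parameters
#' exceeding R-hat 1.01 or falling below ESS 400 trigger a warning (the fit
#' is still returned, flagged).
#'
#' @param trials Trial tibble with columns `subject_id`, `puck_id`, `x`,
#'   `t_pre` (one or more subjects; each needs at least two trials per
#'   puck).
#' @param spec An [interaction_spec()].
#' @return An object of class `interaction_fit` with elements `draws`
#'   (long tibble: `subject_id`, `chain`, `draw`, `parameter`, `value`),
#'   `map` (tibble of MAP parameter values per subject), `map_x_per`
#'   (list of MAP percept vectors per subject), `diagnostics`, and `spec`.
#' @export
fit_interaction <- function(trials, spec = interaction_spec()) {
  stopifnot(inherits(spec, "interaction_spec"))
  needed <- c("subject_id", "puck_id", "x", "t_pre")
  if (!all(needed %in% names(trials))) {
    stop("`trials` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  counts <- dplyr::count(trials, .data$subject_id, .data$puck_id)
  if (any(counts$n < 2)) {
    stop("each fitted puck needs at least 2 trials", call. = FALSE)
  }
  subjects <- unique(trials$subject_id)
  fits <- lapply(subjects, function(sid) {
    dat <- trials[trials$subject_id == sid, ]
    sample_interaction_subject(dat, spec,
                               seed = derive_seed(spec$mcmc$seed, sid))
  })
  names(fits) <- subjects
  draws <- purrr::map_dfr(subjects, function(sid) {
    dplyr::mutate(fits[[sid]]$draws, subject_id = sid, .before = 1)
  })
  maps <- purrr::map_dfr(subjects, function(sid) {
    dplyr::mutate(fits[[sid]]$map, subject_id = sid, .before = 1)
  })
  diagnostics <- purrr::map_dfr(subjects, function(sid) {
    dplyr::mutate(fits[[sid]]$diagnostics, subject_id = sid, .before = 1)
  })
  bad <- diagnostics[!is.na(diagnostics$rhat) &
                       (diagnostics$rhat > 1.01 | diagnostics$ess < 400), ]
  if (nrow(bad) > 0) {
    warning(sprintf(
      "possible non-convergence for %d parameter(s) (max rhat %.3f, min ess %.0f)",
      nrow(bad), max(bad$rhat), min(bad$ess, na.rm = TRUE)
    ), call. = FALSE)
  }
  structure(
    list(draws = draws, map = maps,
         map_x_per = lapply(fits, `[[`, "map_x_per"),
         diagnostics = diagnostics, spec = spec,
         converged = nrow(bad) == 0),
    class = "interaction_fit"
  )
}

# Sampler for a single subject's trials. Parameterised on the log scale for
# the positive parameters; the percept latents are z = log(x_per).
sample_interaction_subject <- function(dat, spec, seed) {
  env <- spec$env
  lt <- log(dat$t_pre)
  lx <- log(dat$x)
  puck <- as.character(dat$puck_id)
  pucks <- unique(puck)
  idx <- lapply(pucks, function(p) which(puck == p))
  names(idx) <- pucks
  n <- length(lt)
  b <- if (spec$model_class == "newtonian") 0.5 else 1
  par_name <- if (spec$model_class == "newtonian") "mass" else "linear_factor"
  pr_par <- spec$priors[[par_name]]
  pr_st <- spec$priors$sigma_t
  pr_sx <- spec$priors$sigma_x
  base_const <- if (spec$model_class == "newtonian") {
    -log(env$interaction_force) +
      0.5 * log(2 * env$friction_coefficient * env$gravity)
  } else {
    0
  }
  fixed_st <- spec$sigma_t_fixed
  fixed_sx <- spec$sigma_x_fixed
  mc <- spec$mcmc
  n_iter <- mc$warmup + mc$draws

  # data-driven initial values (robust under all cost shifts)
  init_lpar <- vapply(pucks, function(p) {
    i <- idx[[p]]
    stats::median(lt[i] - base_const - b * lx[i])
  }, numeric(1))

  # marginal log-likelihood of trial subset i (percept integrated out)
  marg_ll <- function(i, lpar_i, sig_t, sig_x) {
    ml <- base_const + lpar_i + b * (lx[i] + sig_x^2) +
      cost_shift(spec$cost_function, sig_t)
    sum(stats::dnorm(lt[i], ml, sqrt(sig_t^2 + b^2 * sig_x^2), log = TRUE))
  }

  run_chain <- function(chain_seed, jitter) {
    withr_seed(chain_seed, {
      lpar <- init_lpar + jitter * stats::rnorm(length(pucks), 0, 0.1)
      sig_t <- if (is.null(fixed_st)) 0.2 * exp(jitter * stats::rnorm(1, 0, 0.2)) else fixed_st
      sig_x <- if (is.null(fixed_sx)) 0.05 * exp(jitter * stats::rnorm(1, 0, 0.2)) else fixed_sx
      z <- lx + sig_x^2
      scales <- rep(-2, length(pucks) + 2) # log proposal scales
      keep <- matrix(NA_real_, mc$draws, length(pucks) + 2 + 1)
      map <- list(lp = -Inf)

      for (it in seq_len(n_iter)) {
        gain <- if (it <= mc$warmup) 2 / sqrt(it) else 0

        # collapsed updates: parameters against the analytic percept-
        # marginal posterior (the latents are re-drawn exactly below, so
        # the sampled joint is unchanged but the parameters mix freely)
        for (j in seq_along(pucks)) {
          i <- idx[[pucks[j]]]
          lp_fun <- function(lp_j) {
            marg_ll(i, lp_j, sig_t, sig_x) +
              stats::dgamma(exp(lp_j), pr_par[1], pr_par[2], log = TRUE) + lp_j
          }
          st <- rw_step(lpar[j], scales[j], lp_fun, lp_fun(lpar[j]), gain)
          lpar[j] <- st$value
          scales[j] <- st$log_scale
        }

        lpar_all <- lpar[match(puck, pucks)]

        if (is.null(fixed_st)) {
          j <- length(pucks) + 1
          lp_fun <- function(ls) {
            s <- exp(ls)
            marg_ll(seq_len(n), lpar_all, s, sig_x) +
              stats::dgamma(s, pr_st[1], pr_st[2], log = TRUE) + ls
          }
          st <- rw_step(log(sig_t), scales[j], lp_fun, lp_fun(log(sig_t)), gain)
          sig_t <- exp(st$value)
          scales[j] <- st$log_scale
        }

        if (is.null(fixed_sx)) {
          j <- length(pucks) + 2
          lp_fun <- function(ls) {
            s <- exp(ls)
            marg_ll(seq_len(n), lpar_all, sig_t, s) +
              stats::dgamma(s, pr_sx[1], pr_sx[2], log = TRUE) + ls
          }
          st <- rw_step(log(sig_x), scales[j], lp_fun, lp_fun(log(sig_x)), gain)
          sig_x <- exp(st$value)
          scales[j] <- st$log_scale
        }

        # exact Gibbs for the log-percepts given the parameters
        s_c <- cost_shift(spec$cost_function, sig_t)
        base_i <- base_const + lpar[match(puck, pucks)]
        prec <- 1 / sig_x^2 + b^2 / sig_t^2
        mu_post <- ((lx + sig_x^2) / sig_x^2 +
                      b * (lt - base_i - s_c) / sig_t^2) / prec
        z <- mu_post + stats::rnorm(n, 0, sqrt(1 / prec))

        if (it > mc$warmup) {
          # MAP bookkeeping uses the percept-marginalised parameter
          # posterior: the joint density with the per-trial latents is
          # unbounded as sigma_x -> 0, so a highest-joint-draw MAP would
          # be degenerate; the marginal is exact and well-behaved
          lp_marg <- marg_ll(seq_len(n), lpar[match(puck, pucks)],
                             sig_t, sig_x) +
            sum(stats::dgamma(exp(lpar), pr_par[1], pr_par[2], log = TRUE))
          if (is.null(fixed_st)) {
            lp_marg <- lp_marg + stats::dgamma(sig_t, pr_st[1], pr_st[2], log = TRUE)
          }
          if (is.null(fixed_sx)) {
            lp_marg <- lp_marg + stats::dgamma(sig_x, pr_sx[1], pr_sx[2], log = TRUE)
          }
          keep[it - mc$warmup, ] <- c(exp(lpar), sig_t, sig_x, lp_marg)
          if (lp_marg > map$lp) {
            map <- list(lp = lp_marg, pars = exp(lpar), sig_t = sig_t,
                        sig_x = sig_x, x_per = exp(z))
          }
        }
      }
      colnames(keep) <- c(paste0(par_name, "[", pucks, "]"),
                          "sigma_t", "sigma_x", "lp")
      list(keep = keep, map = map)
    })
  }

  chains <- lapply(seq_len(mc$chains), function(cid) {
    run_chain(seed + cid, jitter = as.numeric(cid > 1))
  })

  par_cols <- colnames(chains[[1]]$keep)
  sampled_cols <- setdiff(par_cols, c(
    "lp",
    if (!is.null(fixed_st)) "sigma_t",
    if (!is.null(fixed_sx)) "sigma_x"
  ))
  draw_mats <- lapply(sampled_cols, function(pc) {
    sapply(chains, function(ch) ch$keep[, pc])
  })
  names(draw_mats) <- sampled_cols
  diagnostics <- mcmc_diagnostics(draw_mats)

  draws <- purrr::map_dfr(seq_along(chains), function(cid) {
    k <- chains[[cid]]$keep
    tibble::tibble(
      chain = cid,
      draw = rep(seq_len(nrow(k)), times = ncol(k)),
      parameter = rep(colnames(k), each = nrow(k)),
      value = as.vector(k)
    )
  })

  best <- which.max(vapply(chains, function(ch) ch$map$lp, numeric(1)))
  mp <- chains[[best]]$map
  map <- tibble::tibble(
    parameter = c(paste0(par_name, "[", pucks, "]"), "sigma_t", "sigma_x", "lp"),
    value = c(mp$pars, mp$sig_t, mp$sig_x, mp$lp)
  )
  list(draws = draws, map = map, map_x_per = mp$x_per, diagnostics = diagnostics)
}

#' Pin nuisance parameters from a feedback-phase fit
#'
#' Extracts one shared perceptual variability (the mean of the per-subject
#' `sigma_x` MAPs — perceptual variability is consistent across subjects,
#' so a single constant is reused downstream) and the per-subject press-time
#' variability MAPs, for reuse as fixed values when analysing the other
#' phases.
#'
#' @param fit An [fit_interaction()] result on feedback-phase data.
#' @return A list with `sigma_x` (scalar) and `sigma_t` (tibble
#'   `subject_id`, `sigma_t`).
#' @export
fix_nuisance <- function(fit) {
  stopifnot(inherits(fit, "interaction_fit"))
  maps <- fit$map
  sx <- maps[maps$parameter == "sigma_x", ]
  st <- maps[maps$parameter == "sigma_t", ]
  if (nrow(sx) == 0 || nrow(st) == 0) {
    stop("fit does not contain sigma_x / sigma_t MAPs", call. = FALSE)
  }
  list(
    sigma_x = mean(sx$value),
    sigma_t = tibble::tibble(subject_id = st$subject_id, sigma_t = st$value)
  )
}

#' Posterior predictive press-times
#'
#' For `n_draws` retained posterior draws (evenly spaced through the chains)
#' regenerates a press-time for every trial through the full generative
#' path: percept sample, intended press-time at the draw's mass (or slope),
#' cost shift, and log-normal motor noise.
#'
#' @param fit An [fit_interaction()] result.
#' @param trials The trial tibble the fit was computed on.
#' @param n_draws Number of posterior draws to simulate from (default 50).
#' @param seed Integer seed for the predictive simulation.
#' @return Tibble with `draw`, `subject_id`, `trial_index`, `puck_id`,
#'   `x`, `t_pred`.
#' @export
posterior_predictive_press_times <- function(fit, trials, n_draws = 50,
                                             seed = 1L) {
  stopifnot(inherits(fit, "interaction_fit"))
  if (n_draws < 1) stop("`n_draws` must be at least 1", call. = FALSE)
  spec <- fit$spec
  par_name <- if (spec$model_class == "newtonian") "mass" else "linear_factor"
  withr_seed(seed, {
    purrr::map_dfr(unique(trials$subject_id), function(sid) {
      dat <- trials[trials$subject_id == sid, ]
      dr <- fit$draws[fit$draws$subject_id == sid, ]
      wide <- tidyr::pivot_wider(dr, names_from = "parameter",
                                 values_from = "value")
      take <- unique(round(seq(1, nrow(wide), length.out = n_draws)))
      purrr::map_dfr(seq_along(take), function(d) {
        row <- wide[take[d], ]
        sig_t <- if (is.null(spec$sigma_t_fixed)) row$sigma_t else spec$sigma_t_fixed
        sig_x <- if (is.null(spec$sigma_x_fixed)) row$sigma_x else spec$sigma_x_fixed
        pars <- unlist(row[paste0(par_name, "[", unique(dat$puck_id), "]")])
        names(pars) <- unique(dat$puck_id)
        x_per <- perceive_distance(dat$x, sig_x)
        t_int <- if (spec$model_class == "newtonian") {
          intended_press_time(x_per, "newtonian",
                              mass_belief = pars[as.character(dat$puck_id)],
                              env = spec$env)
        } else {
          pars[as.character(dat$puck_id)] * x_per
        }
        tibble::tibble(
          draw = d, subject_id = sid, trial_index = dat$trial_index,
          puck_id = dat$puck_id, x = dat$x,
          t_pred = emit_press_time(t_int, sig_t, spec$cost_function)
        )
      })
    })
  })
}

#' Residuals of observed press-times against the fitted model
#'
#' The predicted press-time for a trial is the cost-optimal intended
#' press-time at the MAP parameters evaluated at the trial's true distance
#' (the model's systematic prediction); the residual is observed minus
#' predicted. A model class matching the generative process leaves no
#' distance trend in the residuals, whereas a misspecified class (e.g. a
#' linear fit to square-root data) produces residuals that correlate with
#' distance.
#'
#' @param fit An [fit_interaction()] result.
#' @param trials The trial tibble the fit was computed on (>= 3 trials).
#' @return A list with `residuals` (tibble: `subject_id`, `trial_index`,
#'   `puck_id`, `x`, `t_pre`, `t_pred`, `residual`), the pooled Spearman
#'   `rho` of residual against distance, its `p_value`, and `degenerate`
#'   (`TRUE` when the residuals are constant and the correlation is
#'   reported as 0).
#' @export
residual_analysis <- function(fit, trials) {
  stopifnot(inherits(fit, "interaction_fit"))
  if (nrow(trials) < 3) stop("need at least 3 trials", call. = FALSE)
  spec <- fit$spec
  par_name <- if (spec$model_class == "newtonian") "mass" else "linear_factor"
  res <- purrr::map_dfr(unique(trials$subject_id), function(sid) {
    dat <- trials[trials$subject_id == sid, ]
    maps <- fit$map[fit$map$subject_id == sid, ]
    getv <- function(p) maps$value[maps$parameter == p]
    pars <- vapply(unique(as.character(dat$puck_id)), function(p) {
      getv(paste0(par_name, "[", p, "]"))
    }, numeric(1))
    t_pred <- if (spec$model_class == "newtonian") {
      intended_press_time(dat$x, "newtonian",
                          mass_belief = pars[as.character(dat$puck_id)],
                          env = spec$env)
    } else {
      pars[as.character(dat$puck_id)] * dat$x
    }
    tibble::tibble(
      subject_id = sid, trial_index = dat$trial_index, puck_id = dat$puck_id,
      x = dat$x, t_pre = dat$t_pre, t_pred = t_pred,
      residual = dat$t_pre - t_pred
    )
  })
  if (stats::sd(res$residual) == 0) {
    return(list(residuals = res, rho = 0, p_value = NA_real_,
                degenerate = TRUE))
  }
  ct <- suppressWarnings(
    stats::cor.test(res$residual, res$x, method = "spearman")
  )
  list(residuals = res, rho = unname(ct$estimate), p_value = ct$p.value,
       degenerate = FALSE)
}
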