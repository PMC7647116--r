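# Bayesian observation model: inferring the unknown puck's mass from
# watched elastic collisions.

#' Specification of the collision observation model
#'
#' Describes the generative model of perceiving elastic collisions: each
#' pre-collision velocity is perceived through a log-normal with log-scale
#' `sigma_vel` and mode at the actual velocity; the perceived post-collision
#' velocities are anchored at the elastic-collision prediction computed from
#' the perceived pre-collision velocities and the masses, with the observed
#' post-collision velocities as their measured values. Mass beliefs for the
#' known pucks and the unknown puck are gamma priors, typically
#' moment-matched from interaction-model posteriors.
#'
#' @param sigma_vel Log-scale SD of the velocity percepts (default 0.2).
#' @param prior_mass_NF `c(shape, rate)` gamma prior for the unknown mass,
#'   or a numeric vector of posterior samples to moment-match a gamma to.
#' @param prior_mass_F Named list (by known puck id) of `c(shape, rate)`
#'   gamma priors, or sample vectors to moment-match.
#' @param fix_mass_F If `TRUE`, the known masses are fixed at their prior
#'   means instead of being sampled.
#' @param chains,warmup,draws,seed MCMC settings.
#' @return An object of class `observation_spec`.
#' @export
observation_spec <- function(sigma_vel = 0.2,
                             prior_mass_NF = c(shape = 4, rate = 2),
                             prior_mass_F = NULL,
                             fix_mass_F = FALSE,
                             chains = 2L, warmup = 700L, draws = 1500L,
                             seed = 1L) {
  stopifnot(sigma_vel > 0, chains >= 1, warmup >= 0, draws >= 1)
  structure(
    list(
      sigma_vel = sigma_vel,
      prior_mass_NF = as_gamma_prior(prior_mass_NF),
      prior_mass_F = if (!is.null(prior_mass_F)) {
        lapply(prior_mass_F, as_gamma_prior)
      },
      fix_mass_F = isTRUE(fix_mass_F),
      mcmc = list(chains = as.integer(chains), warmup = as.integer(warmup),
                  draws = as.integer(draws), seed = as.integer(seed))
    ),
    class = "observation_spec"
  )
}

#' Moment-match a gamma distribution to posterior samples
#'
#' Converts an empirical sample (e.g. interaction-model posterior mass
#' draws) into `c(shape, rate)` gamma hyperparameters with the same mean
#' and variance; keeps the support positive and the prior family consistent
#' with the interaction model. A length-2 named/unnamed vector is returned
#' unchanged (already hyperparameters).
#'
#' @param x Numeric sample vector (length > 2), or `c(shape, rate)`.
#' @return Named numeric `c(shape, rate)`.
#' @export
as_gamma_prior <- function(x) {
  if (length(x) == 2) {
    out <- c(shape = unname(x[1]), rate = unname(x[2]))
    stopifnot(all(out > 0))
    return(out)
  }
  stopifnot(length(x) > 2, all(x > 0))
  m <- mean(x)
  v <- stats::var(x)
  c(shape = m^2 / v, rate = m / v)
}

# meanlog putting the log-normal mode at `value`
mode_meanlog <- function(value, sdlog) log(value) + sdlog^2

#' Log joint density of the observation model
#'
#' Sum over collisions of the log-normal percept terms for the pre-collision
#' velocities (mode at the actual velocity), the log-normal terms for the
#' observed post-collision velocities anchored at the elastic-collision
#' prediction from the perceived pre-velocities and the masses, plus the
#' gamma mass priors. Values outside the support return `-Inf`.
#'
#' @param events Collision tibble with `known_puck_id`, `vF`, `vNF`, `uF`,
#'   `uNF`, `mF` (as from [generate_collisions()]).
#' @param latents Named list: `vF_per`, `vNF_per` (length `nrow(events)`),
#'   `mNF` (scalar), `mF` (named by known puck id; defaults to the events'
#'   `mF` column when absent).
#' @param spec An [observation_spec()].
#' @return Scalar log density.
#' @export
log_joint_observation <- function(events, latents, spec) {
  stopifnot(inherits(spec, "observation_spec"))
  sv <- spec$sigma_vel
  vF_per <- latents$vF_per
  vNF_per <- latents$vNF_per
  mNF <- latents$mNF
  if (length(vF_per) != nrow(events) || length(vNF_per) != nrow(events)) {
    stop("percept latents must have one value per collision", call. = FALSE)
  }
  if (mNF <= 0 || any(vF_per <= 0) || any(vNF_per <= 0)) return(-Inf)
  mF <- if (!is.null(latents$mF)) {
    unname(latents$mF[as.character(events$known_puck_id)])
  } else {
    events$mF
  }
  if (any(mF <= 0)) return(-Inf)
  pred <- elastic_collision(vF_per, vNF_per, mF, mNF)
  if (any(pred$uF <= 0) || any(pred$uNF <= 0)) return(-Inf)
  lp <- sum(stats::dlnorm(vF_per, mode_meanlog(events$vF, sv), sv, log = TRUE)) +
    sum(stats::dlnorm(vNF_per, mode_meanlog(events$vNF, sv), sv, log = TRUE)) +
    sum(stats::dlnorm(events$uF, mode_meanlog(pred$uF, sv), sv, log = TRUE)) +
    sum(stats::dlnorm(events$uNF, mode_meanlog(pred$uNF, sv), sv, log = TRUE))
  pr <- spec$prior_mass_NF
  lp <- lp + stats::dgamma(mNF, pr[1], pr[2], log = TRUE)
  if (!is.null(latents$mF) && !is.null(spec$prior_mass_F)) {
    for (p in names(latents$mF)) {
      g <- spec$prior_mass_F[[p]]
      if (!is.null(g)) {
        lp <- lp + stats::dgamma(latents$mF[[p]], g[1], g[2], log = TRUE)
      }
    }
  }
  lp
}

#' Fit the observation model by MCMC
#'
#' Samples the unknown puck's mass, the known-puck mass beliefs (unless
#' fixed) and the perceived pre-collision velocities with adaptive
#' random-walk Metropolis on the log scale (element-wise for the percepts).
#'
#' @param events Collision tibble (as from [generate_collisions()]; at
#'   least one collision).
#' @param spec An [observation_spec()]. When `prior_mass_F` is `NULL`,
#'   tight priors centred on the events' `mF` column are used.
#' @return An object of class `observation_fit`: `draws` (long tibble
#'   `chain`, `draw`, `parameter`, `value`), `summary` (tibble with
#'   posterior mean, variance, and MAP of `mNF`), `map` (list of MAP
#'   latents), `diagnostics`, `spec`.
#' @export
fit_observation <- function(events, spec = observation_spec()) {
  stopifnot(inherits(spec, "observation_spec"))
  if (nrow(events) < 1) stop("need at least one collision", call. = FALSE)
  pucks <- unique(as.character(events$known_puck_id))
  prior_F <- spec$prior_mass_F
  if (is.null(prior_F)) {
    # default: tight beliefs at the true known masses (5% SD)
    prior_F <- lapply(pucks, function(p) {
      m <- events$mF[events$known_puck_id == p][1]
      as_gamma_prior(c(shape = 400, rate = 400 / m))
    })
    names(prior_F) <- pucks
  }
  spec$prior_mass_F <- prior_F
  n <- nrow(events)
  k <- as.character(events$known_puck_id)
  sv <- spec$sigma_vel
  mc <- spec$mcmc
  n_iter <- mc$warmup + mc$draws
  pr_NF <- spec$prior_mass_NF
  prior_F_mean <- vapply(prior_F, function(g) g[1] / g[2], numeric(1))

  run_chain <- function(chain_seed, jitter) {
    withr_seed(chain_seed, {
      zF <- log(events$vF) + jitter * stats::rnorm(n, 0, 0.05)
      zNF <- log(events$vNF) + jitter * stats::rnorm(n, 0, 0.05)
      lmNF <- log(pr_NF[1] / pr_NF[2]) + jitter * stats::rnorm(1, 0, 0.1)
      lmF <- log(prior_F_mean)
      scale_z <- rep(-2, 2 * n)
      scale_m <- rep(-2.5, 1 + length(pucks))
      keep <- matrix(NA_real_, mc$draws, 1 + length(pucks) + 1)
      map <- list(lp = -Inf)

      lp_of <- function(zF, zNF, lmNF, lmF) {
        log_joint_observation(
          events,
          list(vF_per = exp(zF), vNF_per = exp(zNF), mNF = exp(lmNF),
               mF = stats::setNames(exp(lmF), pucks)),
          spec
        ) + sum(zF) + sum(zNF) + lmNF + sum(lmF) # log-scale Jacobians
      }
      lp_cur <- lp_of(zF, zNF, lmNF, lmF)

      for (it in seq_len(n_iter)) {
        gain <- if (it <= mc$warmup) 2 / sqrt(it) else 0

        # element-wise MH on the percepts (joint term is per-collision, but
        # a whole-vector proposal with per-element acceptance needs the
        # per-collision decomposition; propose per element block instead)
        prop_zF <- zF + exp(scale_z[seq_len(n)]) * stats::rnorm(n)
        prop_zNF <- zNF + exp(scale_z[n + seq_len(n)]) * stats::rnorm(n)
        mF_now <- unname(exp(lmF)[match(k, pucks)])
        cur_terms <- collision_terms(events, exp(zF), exp(zNF), mF_now,
                                     exp(lmNF), sv) + zF + zNF
        prop_terms <- collision_terms(events, exp(prop_zF), exp(prop_zNF),
                                      mF_now, exp(lmNF), sv) +
          prop_zF + prop_zNF
        acc <- log(stats::runif(n)) < (prop_terms - cur_terms)
        acc[!is.finite(prop_terms)] <- FALSE
        zF[acc] <- prop_zF[acc]
        zNF[acc] <- prop_zNF[acc]
        if (gain > 0) {
          ap <- pmin(1, exp(prop_terms - cur_terms))
          ap[!is.finite(ap)] <- 0
          scale_z[seq_len(n)] <- scale_z[seq_len(n)] + gain * (ap - 0.44)
          scale_z[n + seq_len(n)] <- scale_z[n + seq_len(n)] + gain * (ap - 0.44)
        }
        lp_cur <- lp_of(zF, zNF, lmNF, lmF)

        st <- rw_step(lmNF, scale_m[1],
                      function(v) lp_of(zF, zNF, v, lmF), lp_cur, gain)
        lmNF <- st$value
        scale_m[1] <- st$log_scale
        lp_cur <- st$lp

        if (!spec$fix_mass_F) {
          for (j in seq_along(pucks)) {
            st <- rw_step(lmF[j], scale_m[1 + j], function(v) {
              lmF2 <- lmF
              lmF2[j] <- v
              lp_of(zF, zNF, lmNF, lmF2)
            }, lp_cur, gain)
            lmF[j] <- st$value
            scale_m[1 + j] <- st$log_scale
            lp_cur <- st$lp
          }
        }

        if (it > mc$warmup) {
          keep[it - mc$warmup, ] <- c(exp(lmNF), exp(lmF), lp_cur)
          if (lp_cur > map$lp) {
            map <- list(lp = lp_cur, mNF = exp(lmNF),
                        mF = stats::setNames(exp(lmF), pucks),
                        vF_per = exp(zF), vNF_per = exp(zNF))
          }
        }
      }
      colnames(keep) <- c("mNF", paste0("mF[", pucks, "]"), "lp")
      list(keep = keep, map = map)
    })
  }

  chains <- lapply(seq_len(mc$chains), function(cid) {
    run_chain(derive_seed(mc$seed, paste0("obs", cid)), jitter = as.numeric(cid > 1))
  })

  sampled_cols <- c("mNF", if (!spec$fix_mass_F) paste0("mF[", pucks, "]"))
  draw_mats <- lapply(sampled_cols, function(pc) {
    sapply(chains, function(ch) ch$keep[, pc])
  })
  names(draw_mats) <- sampled_cols
  diagnostics <- mcmc_diagnostics(draw_mats)
  bad <- diagnostics[!is.na(diagnostics$rhat) &
                       (diagnostics$rhat > 1.01 | diagnostics$ess < 400), ]
  if (nrow(bad) > 0) {
    warning(sprintf(
      "possible non-convergence for %d observation-model parameter(s)",
      nrow(bad)
    ), call. = FALSE)
  }

  draws <- purrr::map_dfr(seq_along(chains), function(cid) {
    kp <- chains[[cid]]$keep
    tibble::tibble(
      chain = cid,
      draw = rep(seq_len(nrow(kp)), times = ncol(kp)),
      parameter = rep(colnames(kp), each = nrow(kp)),
      value = as.vector(kp)
    )
  })
  mnf <- draws$value[draws$parameter == "mNF"]
  best <- which.max(vapply(chains, function(ch) ch$map$lp, numeric(1)))
  structure(
    list(
      draws = draws,
      summary = tibble::tibble(
        parameter = "mNF", mean = mean(mnf), variance = stats::var(mnf),
        map = chains[[best]]$map$mNF
      ),
      map = chains[[best]]$map,
      diagnostics = diagnostics,
      converged = nrow(bad) == 0,
      spec = spec
    ),
    class = "observation_fit"
  )
}

# Per-collision log terms involving the percepts (vectorised; -Inf rows for
# invalid predictions).
collision_terms <- function(events, vF_per, vNF_per, mF, mNF, sv) {
  pred <- elastic_collision(vF_per, vNF_per, mF, mNF)
  out <- stats::dlnorm(vF_per, mode_meanlog(events$vF, sv), sv, log = TRUE) +
    stats::dlnorm(vNF_per, mode_meanlog(events$vNF, sv), sv, log = TRUE)
  ok <- pred$uF > 0 & pred$uNF > 0
  out[!ok] <- -Inf
  out[ok] <- out[ok] +
    stats::dlnorm(events$uF[ok], mode_meanlog(pred$uF[ok], sv), sv, log = TRUE) +
    stats::dlnorm(events$uNF[ok], mode_meanlog(pred$uNF[ok], sv), sv, log = TRUE)
  out
}

#' Posterior variance of the unknown mass along collision prefixes
#'
#' Refits the observation model on the first `checkpoints[i]` collisions
#' and reports the posterior variance of the unknown mass at each
#' checkpoint; in expectation over seeds the variance is non-increasing in
#' the number of observed collisions.
#'
#' @param events Collision tibble.
#' @param spec An [observation_spec()].
#' @param checkpoints Increasing integer vector of prefix lengths
#'   (default `c(6, 24)`), each at most `nrow(events)`.
#' @return Tibble with `n_collisions`, `variance`, `mean`, `map`.
#' @export
uncertainty_trajectory <- function(events, spec = observation_spec(),
                                   checkpoints = c(6, 24)) {
  if (any(checkpoints > nrow(events))) {
    stop("checkpoints exceed the number of collisions", call. = FALSE)
  }
  purrr::map_dfr(checkpoints, function(nc) {
    fit <- suppressWarnings(fit_observation(events[seq_len(nc), ], spec))
    tibble::tibble(
      n_collisions = nc,
      variance = fit$summary$variance,
      mean = fit$summary$mean,
      map = fit$summary$map
    )
  })
}
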