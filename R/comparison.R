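# Model comparison: product-space Bayes factors, distributional checks
# (Kolmogorov-Smirnov, Kullback-Leibler), Bayesian change-point detection.

#' Product-space Bayes factor between the newtonian and linear classes
#'
#' Runs a trans-model MCMC in which a latent index selects, at each
#' iteration, whether the newtonian or the linear model class explains the
#' press-times. Conditional on the index, the active model's parameters are
#' updated against the marginal press-time likelihood (the per-trial percept
#' integrated out analytically, [press_time_marginal_loglik()]) while the
#' inactive model's parameters are drawn from pseudo-priors; the index is
#' then Gibbs-sampled. With equal prior model probabilities the Bayes factor
#' `K` (newtonian : linear) equals the posterior odds of the index.
#'
#' Pseudo-priors are set from short pilot single-model fits (log-normal
#' moment matches of the pilot posteriors), the standard device for keeping
#' the index variable mobile. If the index never visits one model, `K` is
#' reported at the `(count + 0.5)` bound and flagged.
#'
#' @param trials Trial tibble (one or more subjects) with `subject_id`,
#'   `puck_id`, `x`, `t_pre`. Zero-row input returns the prior odds.
#' @param spec_newtonian,spec_linear [interaction_spec()] objects for the
#'   two classes (their `cost_function`, priors and env are used; their
#'   `sigma_x_fixed` should normally be set).
#' @param prior_prob_newtonian Prior probability of the newtonian class
#'   (default 0.5).
#' @param iterations Trans-model iterations after warmup.
#' @param warmup Warmup iterations (adaptation + pseudo-prior burn-in).
#' @param pilot_iterations Iterations of each pilot single-model run.
#' @param seed Integer seed.
#' @return An object of class `bayes_factor_report`: a list with `K`
#'   (posterior odds newtonian : linear, prior-odds corrected),
#'   `log10_K`, `visits` (index counts), `bounded` (`TRUE` when one model
#'   was never visited), `interpretation` (`"substantial"` above the 3.2
#'   evidence band, `"anecdotal"` between 1 and 3.2, and the linear-side
#'   mirror labels below 1).
#' @export
product_space_bayes_factor <- function(trials,
                                       spec_newtonian = interaction_spec("newtonian"),
                                       spec_linear = interaction_spec("linear",
                                         cost_function = spec_newtonian$cost_function
                                       ),
                                       prior_prob_newtonian = 0.5,
                                       iterations = 2000L,
                                       warmup = 500L,
                                       pilot_iterations = 1500L,
                                       seed = 1L) {
  stopifnot(prior_prob_newtonian > 0, prior_prob_newtonian < 1)
  if (nrow(trials) == 0) {
    return(bf_report(prior_prob_newtonian / (1 - prior_prob_newtonian),
                     c(newtonian = 0L, linear = 0L), bounded = FALSE))
  }
  subjects <- unique(trials$subject_id)
  dat <- lapply(subjects, function(sid) trials[trials$subject_id == sid, ])

  withr_seed(seed, {
    # pilot single-model runs give initial values and pseudo-priors
    pilots <- lapply(list(spec_newtonian, spec_linear), function(sp) {
      lapply(dat, function(d) pilot_marginal_fit(d, sp, pilot_iterations))
    })
    names(pilots) <- c("newtonian", "linear")

    specs <- list(newtonian = spec_newtonian, linear = spec_linear)
    # state: per model, per subject, named parameter vector (log scale)
    state <- lapply(pilots, function(pm) lapply(pm, `[[`, "last"))
    pseudo <- lapply(pilots, function(pm) lapply(pm, `[[`, "pseudo"))
    scales <- lapply(pilots, function(pm) lapply(pm, `[[`, "scales"))

    loglik_model <- function(model, st) {
      sum(vapply(seq_along(dat), function(j) {
        marginal_loglik_logpar(dat[[j]], st[[j]], specs[[model]])
      }, numeric(1)))
    }
    logprior_model <- function(model, st) {
      sum(vapply(seq_along(dat), function(j) {
        marginal_logprior_logpar(st[[j]], specs[[model]])
      }, numeric(1)))
    }
    logpseudo_model <- function(model, st) {
      sum(vapply(seq_along(dat), function(j) {
        ps <- pseudo[[model]][[j]]
        sum(stats::dnorm(st[[j]], ps$mean, ps$sd, log = TRUE))
      }, numeric(1)))
    }

    index <- "newtonian"
    visits <- c(newtonian = 0L, linear = 0L)
    lprior_idx <- c(newtonian = log(prior_prob_newtonian),
                    linear = log(1 - prior_prob_newtonian))

    for (it in seq_len(warmup + iterations)) {
      gain <- if (it <= warmup) 2 / sqrt(it) else 0
      # update the active model's parameters by MH against lik * prior
      act <- state[[index]]
      for (j in seq_along(dat)) {
        upd <- mh_update_logpars(dat[[j]], act[[j]], specs[[index]],
                                 scales[[index]][[j]], gain)
        act[[j]] <- upd$pars
        scales[[index]][[j]] <- upd$scales
      }
      state[[index]] <- act
      # refresh the inactive model's parameters from its pseudo-prior
      other <- setdiff(names(state), index)
      state[[other]] <- lapply(seq_along(dat), function(j) {
        ps <- pseudo[[other]][[j]]
        stats::rnorm(length(ps$mean), ps$mean, ps$sd)
      })
      for (j in seq_along(dat)) names(state[[other]][[j]]) <- names(pseudo[[other]][[j]]$mean)
      # Gibbs step on the index
      lw <- vapply(names(state), function(m) {
        other_m <- setdiff(names(state), m)
        lprior_idx[[m]] +
          loglik_model(m, state[[m]]) + logprior_model(m, state[[m]]) +
          logpseudo_model(other_m, state[[other_m]])
      }, numeric(1))
      p_new <- 1 / (1 + exp(lw[["linear"]] - lw[["newtonian"]]))
      index <- if (stats::runif(1) < p_new) "newtonian" else "linear"
      if (it > warmup) visits[[index]] <- visits[[index]] + 1L
    }

    bounded <- any(visits == 0L)
    odds_post <- (visits[["newtonian"]] + 0.5) / (visits[["linear"]] + 0.5)
    prior_odds <- prior_prob_newtonian / (1 - prior_prob_newtonian)
    bf_report(odds_post / prior_odds, visits, bounded)
  })
}

bf_report <- function(K, visits, bounded) {
  band <- 3.2 # transition to substantial evidence
  interpretation <- if (K >= band) {
    "substantial (newtonian)"
  } else if (K > 1) {
    "anecdotal (newtonian)"
  } else if (K > 1 / band) {
    "anecdotal (linear)"
  } else {
    "substantial (linear)"
  }
  if (bounded) {
    interpretation <- paste0(interpretation,
                             "; bound only - index never switched")
  }
  structure(
    list(K = unname(K), log10_K = unname(log10(K)), visits = visits,
         bounded = bounded, evidence_band = band,
         interpretation = interpretation),
    class = "bayes_factor_report"
  )
}

#' @export
print.bayes_factor_report <- function(x, ...) {
  cat(sprintf("Bayes factor (newtonian : linear) K = %.3g [%s]\n",
              x$K, x$interpretation))
  cat(sprintf("  index visits: newtonian %d, linear %d\n",
              x$visits[["newtonian"]], x$visits[["linear"]]))
  invisible(x)
}

# --- marginal-likelihood parameter space helpers (log-scale named vectors) ---

logpar_names <- function(dat, spec) {
  par_name <- if (spec$model_class == "newtonian") "mass" else "linear_factor"
  pucks <- unique(as.character(dat$puck_id))
  c(paste0(par_name, "[", pucks, "]"),
    if (is.null(spec$sigma_t_fixed)) "sigma_t")
}

unpack_logpars <- function(lp, dat, spec) {
  par_name <- if (spec$model_class == "newtonian") "mass" else "linear_factor"
  pucks <- unique(as.character(dat$puck_id))
  pars <- exp(lp[paste0(par_name, "[", pucks, "]")])
  names(pars) <- pucks
  sigma_t <- if (is.null(spec$sigma_t_fixed)) {
    exp(lp[["sigma_t"]])
  } else {
    spec$sigma_t_fixed
  }
  sigma_x <- if (is.null(spec$sigma_x_fixed)) 0.05 else spec$sigma_x_fixed
  out <- list(sigma_t = sigma_t, sigma_x = sigma_x)
  out[[par_name]] <- pars
  out
}

marginal_loglik_logpar <- function(dat, lp, spec) {
  press_time_marginal_loglik(dat, unpack_logpars(lp, dat, spec), spec)
}

marginal_logprior_logpar <- function(lp, spec) {
  par_name <- if (spec$model_class == "newtonian") "mass" else "linear_factor"
  pr <- spec$priors[[par_name]]
  is_par <- startsWith(names(lp), par_name)
  out <- sum(stats::dgamma(exp(lp[is_par]), pr[1], pr[2], log = TRUE) +
               lp[is_par])
  if ("sigma_t" %in% names(lp)) {
    prs <- spec$priors$sigma_t
    out <- out + stats::dgamma(exp(lp[["sigma_t"]]), prs[1], prs[2],
                               log = TRUE) + lp[["sigma_t"]]
  }
  out
}

mh_update_logpars <- function(dat, lp, spec, scales, gain) {
  lpost <- function(v) {
    marginal_loglik_logpar(dat, v, spec) + marginal_logprior_logpar(v, spec)
  }
  cur <- lpost(lp)
  for (nm in names(lp)) {
    prop <- lp
    prop[[nm]] <- lp[[nm]] + exp(scales[[nm]]) * stats::rnorm(1)
    lp_prop <- lpost(prop)
    ap <- if (is.finite(lp_prop)) min(1, exp(lp_prop - cur)) else 0
    if (stats::runif(1) < ap) {
      lp <- prop
      cur <- lp_prop
    }
    if (gain > 0) scales[[nm]] <- scales[[nm]] + gain * (ap - 0.44)
  }
  list(pars = lp, scales = scales)
}

# Short single-model MH run on the marginal likelihood; returns the last
# state, per-parameter log-normal pseudo-priors and adapted scales.
pilot_marginal_fit <- function(dat, spec, iterations) {
  nms <- logpar_names(dat, spec)
  par_name <- if (spec$model_class == "newtonian") "mass" else "linear_factor"
  pucks <- unique(as.character(dat$puck_id))
  init <- vapply(pucks, function(p) {
    i <- dat$puck_id == p
    b <- if (spec$model_class == "newtonian") 0.5 else 1
    base <- if (spec$model_class == "newtonian") {
      -log(spec$env$interaction_force) +
        0.5 * log(2 * spec$env$friction_coefficient * spec$env$gravity)
    } else {
      0
    }
    stats::median(log(dat$t_pre[i]) - base - b * log(dat$x[i]))
  }, numeric(1))
  lp <- stats::setNames(numeric(length(nms)), nms)
  lp[paste0(par_name, "[", pucks, "]")] <- init
  if ("sigma_t" %in% nms) lp[["sigma_t"]] <- log(0.2)
  scales <- stats::setNames(rep(-2, length(nms)), nms)
  keep <- matrix(NA_real_, iterations, length(nms),
                 dimnames = list(NULL, nms))
  warm <- max(50L, iterations %/% 3L)
  for (it in seq_len(warm + iterations)) {
    gain <- if (it <= warm) 2 / sqrt(it) else 0
    upd <- mh_update_logpars(dat, lp, spec, scales, gain)
    lp <- upd$pars
    scales <- upd$scales
    if (it > warm) keep[it - warm, ] <- lp
  }
  list(
    last = lp,
    pseudo = list(mean = colMeans(keep),
                  sd = pmax(apply(keep, 2, stats::sd), 1e-3)),
    scales = scales
  )
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Classical two-sample KS statistic (the maximum gap between the two
#' empirical CDFs) with the asymptotic p-value, via [stats::ks.test()].
#'
#' @param a,b Non-empty numeric sample vectors.
#' @return A list with `D` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}

#' Kullback-Leibler divergence between press-time samples
#'
#' Estimates `KL(observed || predictive)` in nats on a shared histogram:
#' both samples are binned over their pooled range (default 50 bins) with
#' add-one smoothing of the counts, and the discrete divergence of the two
#' normalised histograms is returned. The estimator is documented rather
#' than canonical; it is simple, always finite, and shrinks to zero as the
#' two distributions coincide.
#'
#' @param observed,predictive Non-empty numeric samples.
#' @param bins Number of shared histogram bins (default 50).
#' @return Divergence in nats (>= 0 up to smoothing).
#' @export
kl_press_time_divergence <- function(observed, predictive, bins = 50) {
  if (length(observed) == 0 || length(predictive) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  stopifnot(bins >= 2)
  rng <- range(c(observed, predictive))
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  count <- function(x) {
    tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = bins)
  }
  p <- count(observed) + 1
  q <- count(predictive) + 1
  p <- p / sum(p)
  q <- q / sum(q)
  sum(p * log(p / q))
}

#' Bayesian single change-point model for per-trial errors
#'
#' Fits a two-level model to a series of per-trial mean errors: the mean is
#' `mu1` for trials `1..tau` and `mu2` afterwards, with common noise SD.
#' The prior on the change point `tau` is uniform over `1..(n-1)` (`tau`
#' indexes the last trial of the first regime), the level priors are
#' weakly-informative normals, and the noise SD is integrated numerically
#' over a log-spaced grid under a half-Cauchy prior. Everything else is
#' analytic (conjugate normal linear model given `tau` and the SD), so the
#' posterior over `tau` is exact up to the SD quadrature and fully
#' deterministic.
#'
#' @param mean_errors Numeric series of per-trial (absolute) errors,
#'   length >= 3.
#' @param level_prior_sd SD (metres) of the zero-centred normal prior on
#'   the two error levels (default 10, weakly informative).
#' @param sd_prior_scale Scale of the half-Cauchy prior on the noise SD
#'   (default 1 m).
#' @param sd_grid_size Number of quadrature points for the noise SD.
#' @return An object of class `change_point_fit`: a tibble `tau_posterior`
#'   (`tau`, `probability`), `tau_map`, posterior means `mu_before` and
#'   `mu_after`, and `diffuse` (`TRUE` when the posterior is close to
#'   uniform, e.g. for a constant series).
#' @export
change_point_fit <- function(mean_errors, level_prior_sd = 10,
                             sd_prior_scale = 1, sd_grid_size = 60) {
  y <- as.numeric(mean_errors)
  n <- length(y)
  if (n < 3) stop("need at least 3 trials", call. = FALSE)
  taus <- seq_len(n - 1)
  s_y <- stats::sd(y)
  if (!is.finite(s_y) || s_y == 0) s_y <- max(abs(y), 1e-3)
  log_sigma <- seq(log(s_y / 30), log(s_y * 10), length.out = sd_grid_size)
  sigma <- exp(log_sigma)
  # half-Cauchy prior density on sigma, times sigma (log-grid measure)
  lw_sigma <- stats::dcauchy(sigma, 0, sd_prior_scale, log = TRUE) + log_sigma

  # conjugate marginal of a constant-mean segment given sigma:
  # y_seg ~ N(mu, sigma^2), mu ~ N(0, level_prior_sd^2)
  seg_marginal <- function(y_seg, sig) {
    m <- length(y_seg)
    v0 <- level_prior_sd^2
    vn <- 1 / (1 / v0 + m / sig^2)
    mn <- vn * sum(y_seg) / sig^2
    -0.5 * m * log(2 * pi * sig^2) + 0.5 * log(vn / v0) -
      0.5 * (sum(y_seg^2) / sig^2 - mn^2 / vn)
  }
  post_mean_seg <- function(y_seg, sig) {
    m <- length(y_seg)
    v0 <- level_prior_sd^2
    vn <- 1 / (1 / v0 + m / sig^2)
    vn * sum(y_seg) / sig^2
  }

  lj <- matrix(NA_real_, length(taus), length(sigma))
  for (ti in seq_along(taus)) {
    t_ <- taus[ti]
    for (si in seq_along(sigma)) {
      lj[ti, si] <- seg_marginal(y[seq_len(t_)], sigma[si]) +
        seg_marginal(y[(t_ + 1):n], sigma[si]) + lw_sigma[si]
    }
  }
  lmax <- max(lj)
  joint <- exp(lj - lmax)
  tau_post <- rowSums(joint)
  tau_post <- tau_post / sum(tau_post)
  tau_map <- taus[which.max(tau_post)]

  # posterior mean levels, averaged over (tau, sigma)
  w <- joint / sum(joint)
  mu1 <- 0
  mu2 <- 0
  for (ti in seq_along(taus)) {
    t_ <- taus[ti]
    for (si in seq_along(sigma)) {
      if (w[ti, si] == 0) next
      mu1 <- mu1 + w[ti, si] * post_mean_seg(y[seq_len(t_)], sigma[si])
      mu2 <- mu2 + w[ti, si] * post_mean_seg(y[(t_ + 1):n], sigma[si])
    }
  }

  ent <- -sum(tau_post[tau_post > 0] * log(tau_post[tau_post > 0]))
  diffuse <- ent > 0.9 * log(length(taus))
  if (diffuse) {
    message("change-point posterior is near-uniform (no clear change)")
  }
  structure(
    list(
      tau_posterior = tibble::tibble(tau = taus, probability = tau_post),
      tau_map = tau_map,
      mu_before = mu1,
      mu_after = mu2,
      diffuse = diffuse
    ),
    class = "change_point_fit"
  )
}

#' @export
print.change_point_fit <- function(x, ...) {
  cat(sprintf(
    "Change point MAP tau = %d (P = %.3f)%s\n  mean error before %.3f, after %.3f\n",
    x$tau_map, x$tau_posterior$probability[x$tau_posterior$tau == x$tau_map],
    if (x$diffuse) " [diffuse]" else "", x$mu_before, x$mu_after
  ))
  invisible(x)
}
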