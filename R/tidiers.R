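# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an interaction-model fit
#'
#' One row per subject and parameter with the posterior mean, SD, 95%
#' credible interval, MAP value and convergence diagnostics.
#'
#' @param x An [fit_interaction()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.interaction_fit <- function(x, ...) {
  sm <- x$draws |>
    dplyr::filter(.data$parameter != "lp") |>
    dplyr::group_by(.data$subject_id, .data$parameter) |>
    dplyr::summarise(
      estimate = mean(.data$value),
      std.error = stats::sd(.data$value),
      conf.low = stats::quantile(.data$value, 0.025),
      conf.high = stats::quantile(.data$value, 0.975),
      .groups = "drop"
    )
  maps <- dplyr::rename(x$map, map = "value")
  sm |>
    dplyr::left_join(maps, by = c("subject_id", "parameter")) |>
    dplyr::left_join(x$diagnostics, by = c("subject_id", "parameter"))
}

#' Glance at an interaction-model fit
#'
#' @param x An [fit_interaction()] result.
#' @param ... Unused.
#' @return A one-row tibble: subjects, model class, cost function, draw
#'   count, worst R-hat, smallest ESS, convergence flag.
#' @export
glance.interaction_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = length(unique(x$draws$subject_id)),
    model_class = x$spec$model_class,
    cost_function = x$spec$cost_function,
    n_draws = x$spec$mcmc$chains * x$spec$mcmc$draws,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    min_ess = min(x$diagnostics$ess, na.rm = TRUE),
    converged = x$converged
  )
}

#' @rdname tidy.interaction_fit
#' @export
tidy.observation_fit <- function(x, ...) {
  x$draws |>
    dplyr::filter(.data$parameter != "lp") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      estimate = mean(.data$value),
      std.error = stats::sd(.data$value),
      conf.low = stats::quantile(.data$value, 0.025),
      conf.high = stats::quantile(.data$value, 0.975),
      .groups = "drop"
    ) |>
    dplyr::left_join(x$diagnostics, by = "parameter")
}

#' @rdname glance.interaction_fit
#' @export
glance.observation_fit <- function(x, ...) {
  tibble::tibble(
    mNF_mean = x$summary$mean,
    mNF_variance = x$summary$variance,
    mNF_map = x$summary$map,
    sigma_vel = x$spec$sigma_vel,
    converged = x$converged
  )
}

#' Posterior densities of the mass (or slope) beliefs
#'
#' @param object An [fit_interaction()] result.
#' @param parameters Optional character vector restricting the parameters
#'   shown (defaults to all but the log joint).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.interaction_fit <- function(object, parameters = NULL, ...) {
  d <- dplyr::filter(object$draws, .data$parameter != "lp")
  if (!is.null(parameters)) {
    d <- dplyr::filter(d, .data$parameter %in% parameters)
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value,
                                  colour = .data$subject_id)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free") +
    ggplot2::labs(x = "posterior value", y = "density",
                  colour = "subject") +
    ggplot2::theme_minimal()
}

#' Posterior density of the unknown puck's mass
#'
#' @param object An [fit_observation()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.observation_fit <- function(object, ...) {
  d <- dplyr::filter(object$draws, .data$parameter == "mNF")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::geom_vline(xintercept = object$summary$map, linetype = 2) +
    ggplot2::labs(x = "unknown puck mass (kg)", y = "posterior density") +
    ggplot2::theme_minimal()
}

#' Posterior over the change point
#'
#' @param object A [change_point_fit()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.change_point_fit <- function(object, ...) {
  ggplot2::ggplot(object$tau_posterior,
                  ggplot2::aes(x = .data$tau, y = .data$probability)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_vline(xintercept = object$tau_map, linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "change point (trial)", y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' Press-times against initial distance for a trial table
#'
#' The standard behavioural view: press-times by distance, faceted by phase
#' and condition, with the ideal Newtonian press-time curves of the true
#' masses overlaid.
#'
#' @param trials Trial tibble (as from [simulate_cohort()]).
#' @param env An [env_params()] object for the ideal curves.
#' @return A ggplot object.
#' @export
plot_press_times <- function(trials, env = env_params()) {
  grid <- tidyr::expand_grid(
    condition = unique(trials$condition),
    phase = unique(trials$phase),
    x = seq(env$distance_range[1], env$distance_range[2], length.out = 50)
  )
  ideal <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    masses <- condition_masses(g$condition)
    pucks <- if (g$phase == "feedback") {
      c("yellow-diamond", "red-dots")
    } else if (g$phase == "prior") {
      character(0)
    } else {
      "rings"
    }
    purrr::map_dfr(pucks, function(p) {
      dplyr::mutate(g, puck_id = p,
                    t_ideal = ideal_press_time(g$x, masses[[p]], env))
    })
  })
  ggplot2::ggplot(trials, ggplot2::aes(x = .data$x, y = .data$t_pre)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5) +
    ggplot2::geom_line(
      data = ideal,
      ggplot2::aes(y = .data$t_ideal, colour = .data$puck_id)
    ) +
    ggplot2::facet_grid(ggplot2::vars(.data$condition),
                        ggplot2::vars(.data$phase)) +
    ggplot2::labs(x = "initial distance (m)", y = "press-time (s)",
                  colour = "puck") +
    ggplot2::theme_minimal()
}
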