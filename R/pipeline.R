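# Serialization, validation and the end-to-end synthetic-replication
# pipeline driver.

TRIAL_COLUMNS <- c("subject_id", "condition", "phase", "trial_index",
                   "puck_id", "x", "t_pre", "error", "feedback_shown")
LATENT_COLUMNS <- c("subject_id", "phase", "trial_index", "x_per",
                    "mass_belief", "t_int")
COLLISION_COLUMNS <- c("event_index", "known_puck_id", "vF", "vNF",
                       "uF", "uNF", "mF")

#' Write / read a trial table as CSV
#'
#' The observable columns (`subject_id`, `condition`, `phase`,
#' `trial_index`, `puck_id`, `x`, `t_pre`, `error`, `feedback_shown`) go to
#' `path`; when the tibble carries the ground-truth latent columns
#' (`x_per`, `mass_belief`, `t_int`) they are written to a sidecar CSV
#' `<path>_latents.csv` so recovery analyses can compare against them.
#'
#' @param trials Trial tibble (as from [simulate_cohort()]).
#' @param path CSV file path.
#' @return `path`, invisibly (writer); a trial tibble with, when the
#'   sidecar exists, the latent columns re-joined (reader).
#' @export
write_trial_table <- function(trials, path) {
  readr::write_csv(trials[, intersect(TRIAL_COLUMNS, names(trials))], path)
  if (all(c("x_per", "mass_belief", "t_int") %in% names(trials))) {
    readr::write_csv(trials[, intersect(LATENT_COLUMNS, names(trials))],
                     sidecar_path(path))
  }
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    lat <- readr::read_csv(sc, show_col_types = FALSE)
    out <- dplyr::left_join(out, lat,
                            by = c("subject_id", "phase", "trial_index"))
  }
  out
}

sidecar_path <- function(path) {
  sub("\\.csv$", "_latents.csv", path)
}

#' Write / read a collision-movie table as CSV
#'
#' @param events Collision tibble (as from [generate_collisions()]).
#' @param path CSV file path.
#' @return `path` invisibly (writer); a collision tibble (reader).
#' @export
write_collision_table <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}

#' @rdname write_collision_table
#' @export
read_collision_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Validate a trial table against the schema and invariants
#'
#' Checks the header, the phase labels, the distance range (within the
#' environment's `distance_range`), the positivity of press-times, and that
#' feedback is only flagged in the feedback phase. Returns a
#' machine-readable violation list rather than raising, so callers can
#' report all problems at once.
#'
#' @param x A trial tibble or a CSV path.
#' @param env An [env_params()] object supplying the admissible distance
#'   range.
#' @return A list with `valid` (logical) and `violations` (tibble:
#'   `rule`, `rows`, `message`).
#' @export
validate_trial_table <- function(x, env = env_params()) {
  trials <- if (is.character(x)) {
    if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
    readr::read_csv(x, show_col_types = FALSE)
  } else {
    x
  }
  violations <- list()
  add <- function(rule, rows, msg) {
    violations[[length(violations) + 1]] <<-
      tibble::tibble(rule = rule, rows = list(rows), message = msg)
  }
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols) > 0) {
    add("schema", integer(0),
        paste("missing columns:", paste(missing_cols, collapse = ", ")))
    return(list(valid = FALSE, violations = dplyr::bind_rows(violations)))
  }
  bad <- which(!trials$phase %in% PHASES)
  if (length(bad) > 0) add("phase_labels", bad, "unknown phase label")
  bad <- which(trials$x < env$distance_range[1] |
                 trials$x > env$distance_range[2])
  if (length(bad) > 0) {
    add("distance_range", bad,
        sprintf("x outside [%g, %g] m", env$distance_range[1],
                env$distance_range[2]))
  }
  bad <- which(!is.finite(trials$t_pre) | trials$t_pre <= 0)
  if (length(bad) > 0) add("press_time", bad, "t_pre must be positive")
  bad <- which(trials$feedback_shown & trials$phase != "feedback")
  if (length(bad) > 0) {
    add("feedback_flag", bad, "feedback_shown outside the feedback phase")
  }
  v <- if (length(violations) > 0) dplyr::bind_rows(violations) else {
    tibble::tibble(rule = character(0), rows = list(), message = character(0))
  }
  list(valid = nrow(v) == 0, violations = v)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config Named list of configuration values.
#' @return The configuration list (reader); `path` invisibly (writer).
#' @export
read_pipeline_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param n_subjects Cohort size.
#' @param seed Master seed; all stage seeds are derived substreams.
#' @param chains,warmup,draws MCMC settings shared by the fitting stages.
#' @param outdir Output directory for stage artifacts.
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(n_subjects = 16, seed = 1L, chains = 2L,
                            warmup = 400L, draws = 400L,
                            outdir = tempfile("noisynewton_run_")) {
  list(n_subjects = n_subjects, seed = as.integer(seed),
       chains = as.integer(chains), warmup = as.integer(warmup),
       draws = as.integer(draws), outdir = outdir)
}

#' Run the end-to-end synthetic replication pipeline
#'
#' Generates a cohort, simulates all four phases and the collision movies,
#' fits the feedback phase with both model classes and all three cost
#' functions, pins the nuisance parameters from the quadratic newtonian
#' fit, computes the residual analysis per cost function, the product-space
#' Bayes factor on the feedback data, the change-point analysis of the
#' feedback-phase errors, and the observation-model fit seeded with the
#' interaction posteriors. All artifacts are written under the configured
#' output directory and listed in the returned manifest.
#'
#' @param config A [pipeline_config()] list.
#' @param env An [env_params()] object.
#' @return A list of class `pipeline_manifest`: `config`, `files` (tibble
#'   `stage`, `path`), and `results` (the in-memory stage results).
#' @export
run_pipeline <- function(config = pipeline_config(), env = env_params()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- list()
  note <- function(stage, path) {
    files[[length(files) + 1]] <<- tibble::tibble(stage = stage, path = path)
  }
  results <- list()

  cohort <- make_cohort(config$n_subjects, seed = config$seed)
  dat <- simulate_cohort(cohort, env = env, seed = config$seed)
  p_trials <- file.path(config$outdir, "trials.csv")
  write_trial_table(dat$trials, p_trials)
  note("simulate", p_trials)
  p_coll <- file.path(config$outdir, "collisions.csv")
  write_collision_table(dat$collisions, p_coll)
  note("simulate", p_coll)
  results$cohort <- cohort

  feedback <- dat$trials[dat$trials$phase == "feedback", ]
  fits <- list()
  for (mc_ in c("newtonian", "linear")) {
    for (cf in c("zero_one", "absolute", "quadratic")) {
      key <- paste(mc_, cf, sep = ".")
      sp <- interaction_spec(mc_, cf, env = env, chains = config$chains,
                            warmup = config$warmup, draws = config$draws,
                            seed = derive_seed(config$seed, key))
      fits[[key]] <- suppressWarnings(fit_interaction(feedback, sp))
    }
  }
  results$interaction_fits <- fits
  p_draws <- file.path(config$outdir, "interaction_draws.csv")
  readr::write_csv(
    purrr::map_dfr(names(fits), function(k) {
      dplyr::mutate(fits[[k]]$draws, model = k, .before = 1)
    }),
    p_draws
  )
  note("fit-interaction", p_draws)

  results$nuisance <- fix_nuisance(fits[["newtonian.quadratic"]])
  results$residuals <- lapply(fits, residual_analysis, trials = feedback)

  results$bayes_factor <- product_space_bayes_factor(
    feedback,
    spec_newtonian = interaction_spec("newtonian", "quadratic", env = env,
                                      sigma_x_fixed = results$nuisance$sigma_x),
    spec_linear = interaction_spec("linear", "quadratic", env = env,
                                   sigma_x_fixed = results$nuisance$sigma_x),
    seed = derive_seed(config$seed, "ps")
  )

  err <- dat$trials[dat$trials$phase == "feedback", ]
  err_series <- tapply(abs(err$error), err$trial_index, mean)
  results$change_point <- change_point_fit(as.numeric(err_series))

  first_subj <- cohort$subject_id[1]
  ev <- dat$collisions[dat$collisions$subject_id == first_subj, ]
  fit_q <- fits[["newtonian.quadratic"]]
  prior_F <- lapply(unique(ev$known_puck_id), function(p) {
    d <- fit_q$draws
    as_gamma_prior(d$value[d$subject_id == first_subj &
                             d$parameter == paste0("mass[", p, "]")])
  })
  names(prior_F) <- unique(ev$known_puck_id)
  results$observation <- suppressWarnings(fit_observation(
    ev,
    observation_spec(prior_mass_F = prior_F,
                     seed = derive_seed(config$seed, "obs"))
  ))

  summary_tbl <- tibble::tibble(
    quantity = c("sigma_x_pooled", "bayes_factor_K", "change_point_tau",
                 "observation_mNF_mean"),
    value = c(results$nuisance$sigma_x, results$bayes_factor$K,
              results$change_point$tau_map, results$observation$summary$mean)
  )
  p_summary <- file.path(config$outdir, "summary.csv")
  readr::write_csv(summary_tbl, p_summary)
  note("report", p_summary)
  results$summary <- summary_tbl

  structure(
    list(config = config, files = dplyr::bind_rows(files), results = results),
    class = "pipeline_manifest"
  )
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("<pipeline_manifest>\n")
  cat(sprintf("  %d subjects, seed %d, outputs in %s\n",
              x$config$n_subjects, x$config$seed, x$config$outdir))
  print(x$results$summary)
  invisible(x)
}
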