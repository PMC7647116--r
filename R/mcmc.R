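# Internal MCMC machinery: adaptive Metropolis-within-Gibbs with exact Gibbs
# steps for the per-trial log-percept latents, and convergence diagnostics.

# Split-chain potential scale reduction factor.
split_rhat <- function(draws_matrix) {
  # draws_matrix: iterations x chains
  n <- nrow(draws_matrix)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  splits <- cbind(draws_matrix[seq_len(half), , drop = FALSE],
                  draws_matrix[(n - half + 1):n, , drop = FALSE])
  m <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w <= 0) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Effective sample size via Geyer's initial positive sequence, summed over
# chains (computed on the pooled autocorrelation of centred chains).
ess_basic <- function(draws_matrix) {
  n <- nrow(draws_matrix)
  m <- ncol(draws_matrix)
  if (n < 4) return(NA_real_)
  rho_sum <- 0
  for (c_ in seq_len(m)) {
    x <- draws_matrix[, c_]
    v <- stats::var(x)
    if (v <= 0) next
    ac <- stats::acf(x, lag.max = min(n - 2, 200), plot = FALSE)$acf[-1]
    # initial positive sequence on pair sums
    npair <- floor(length(ac) / 2)
    tau <- 0
    for (p in seq_len(npair)) {
      pair <- ac[2 * p - 1] + ac[2 * p]
      if (pair < 0) break
      tau <- tau + pair
    }
    rho_sum <- rho_sum + tau / m
  }
  (n * m) / (1 + 2 * rho_sum)
}

# One adaptive random-walk Metropolis step on an unconstrained scalar.
# Returns list(value, log_scale, accepted); `logpost` takes the scalar.
rw_step <- function(value, log_scale, logpost, lp_current, adapt_gain) {
  prop <- value + exp(log_scale) * stats::rnorm(1)
  lp_prop <- logpost(prop)
  acc_prob <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp_current)) else 0
  accepted <- stats::runif(1) < acc_prob
  if (adapt_gain > 0) {
    log_scale <- log_scale + adapt_gain * (acc_prob - 0.44)
  }
  if (accepted) {
    list(value = prop, log_scale = log_scale, lp = lp_prop)
  } else {
    list(value = value, log_scale = log_scale, lp = lp_current)
  }
}

# Diagnostics table for an array of draws: list of iteration x chain matrices.
mcmc_diagnostics <- function(draw_mats) {
  tibble::tibble(
    parameter = names(draw_mats),
    rhat = vapply(draw_mats, split_rhat, numeric(1)),
    ess = vapply(draw_mats, ess_basic, numeric(1))
  )
}
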