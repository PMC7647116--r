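# Deterministic Newtonian mechanics: press-time law, frame-based sliding
# under dry friction, and one-dimensional elastic collisions.

#' Physical environment parameters
#'
#' Bundles the physical constants of the simulated sliding surface and the
#' display geometry. A button press of duration `t` applies the constant
#' interaction force `F` to a puck of mass `m`, so the release velocity is
#' `F * t / m`; the puck then decelerates under dry friction `mu * g`.
#'
#' The true constants used in the original virtual environment are not
#' identifiable from behaviour (only mass ratios and the square-root distance
#' scaling are), so the defaults here are conventional values; every analysis
#' in the package conditions on whatever environment it is given.
#'
#' @param friction_coefficient Dimensionless sliding friction coefficient
#'   `mu` (> 0).
#' @param gravity Gravitational acceleration in m/s^2 (> 0).
#' @param interaction_force Constant force applied during the button press,
#'   in newtons (> 0).
#' @param frame_interval Simulation frame interval `dt` in seconds (> 0).
#' @param distance_range Length-2 numeric, metres: the range initial
#'   puck-to-target distances are drawn from.
#' @param pixels_per_metre Display mapping, px/m. The default follows a
#'   1080 px vertical resolution spanning ~11.5 m of simulated surface.
#'
#' @return An object of class `env_params` (a named list).
#' @examples
#' env <- env_params()
#' ideal_press_time(3, mass = 2, env = env)
#' @export
env_params <- function(friction_coefficient = 0.2,
                       gravity = 9.81,
                       interaction_force = 10,
                       frame_interval = 1 / 60,
                       distance_range = c(1, 5),
                       pixels_per_metre = 1080 / 11.5) {
  stopifnot(
    is.numeric(friction_coefficient), friction_coefficient > 0,
    is.numeric(gravity), gravity > 0,
    is.numeric(interaction_force), interaction_force > 0,
    is.numeric(frame_interval), frame_interval > 0,
    length(distance_range) == 2, distance_range[1] < distance_range[2],
    is.numeric(pixels_per_metre), pixels_per_metre > 0
  )
  structure(
    list(
      friction_coefficient = friction_coefficient,
      gravity = gravity,
      interaction_force = interaction_force,
      frame_interval = frame_interval,
      distance_range = as.numeric(distance_range),
      pixels_per_metre = pixels_per_metre
    ),
    class = "env_params"
  )
}

#' @export
print.env_params <- function(x, ...) {
  cat("<env_params>\n")
  cat(sprintf("  mu = %g, g = %g m/s^2, F = %g N, dt = %g s\n",
              x$friction_coefficient, x$gravity, x$interaction_force,
              x$frame_interval))
  cat(sprintf("  distances: [%g, %g] m, display: %.1f px/m\n",
              x$distance_range[1], x$distance_range[2], x$pixels_per_metre))
  invisible(x)
}

#' Ideal press-time to slide a puck a given distance
#'
#' The press-time that propels a puck of mass `m` exactly `distance` metres
#' under friction, assuming perfect knowledge of all constants:
#' `T = (m / F) * sqrt(2 * mu * g * distance)`. The press-time is linear in
#' mass and scales with the square-root of distance.
#'
#' @param distance Distance to the target in metres (>= 0). Vectorised.
#' @param mass Puck mass in kg (> 0).
#' @param env An [env_params()] object.
#' @return Press-time(s) in seconds.
#' @examples
#' ideal_press_time(4, 1.5, env_params()) / ideal_press_time(1, 1.5, env_params()) # 2
#' @export
ideal_press_time <- function(distance, mass, env = env_params()) {
  if (any(!is.finite(distance)) || any(distance < 0)) {
    stop("`distance` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("`mass` must be finite and strictly positive", call. = FALSE)
  }
  (mass / env$interaction_force) *
    sqrt(2 * env$friction_coefficient * env$gravity * distance)
}

#' Release velocity implied by a press-time
#'
#' The button press applies force `F` for duration `t` to mass `m`, so the
#' puck is released at `v0 = F * t / m` (impulse over mass): release velocity
#' scales linearly with press duration.
#'
#' @param press_time Press duration(s) in seconds (>= 0).
#' @inheritParams ideal_press_time
#' @return Release velocity in m/s.
#' @export
release_velocity <- function(press_time, mass, env = env_params()) {
  if (any(!is.finite(press_time)) || any(press_time < 0)) {
    stop("`press_time` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("`mass` must be finite and strictly positive", call. = FALSE)
  }
  env$interaction_force * press_time / mass
}

#' Frame-based simulation of a puck sliding under friction
#'
#' Integrates the sliding motion with the per-frame difference equations
#' `v <- v - mu * g * dt`, `x <- x + v * dt` until the velocity crosses zero.
#' The final partial frame is truncated analytically (the residual distance
#' `v^2 / (2 mu g)` of the last positive velocity is added) so the
#' displacement never overshoots. As `dt -> 0` the displacement converges to
#' the closed-form `v0^2 / (2 mu g)` with error of order `dt`.
#'
#' @param v0 Release velocity, m/s (>= 0).
#' @param env An [env_params()] object; `frame_interval` sets `dt`.
#' @param keep_trajectory If `TRUE`, also return the per-frame trajectory.
#' @return A list with `displacement` (metres) and, if requested,
#'   `trajectory`: a tibble with columns `frame`, `t`, `x`, `v`.
#' @examples
#' simulate_slide(3, env_params())$displacement
#' 3^2 / (2 * 0.2 * 9.81) # closed form
#' @export
simulate_slide <- function(v0, env = env_params(), keep_trajectory = FALSE) {
  if (!is.finite(v0) || v0 < 0) {
    stop("`v0` must be finite and non-negative", call. = FALSE)
  }
  a <- env$friction_coefficient * env$gravity
  dt <- env$frame_interval
  # full frames before the velocity would cross zero
  n <- floor(v0 / (a * dt))
  k <- seq_len(n)
  v_frames <- v0 - k * a * dt
  x <- sum(v_frames) * dt
  v_last <- v0 - n * a * dt # in [0, a*dt)
  x <- x + v_last^2 / (2 * a) # analytic stop within the final frame
  out <- list(displacement = x)
  if (keep_trajectory) {
    out$trajectory <- tibble::tibble(
      frame = c(0L, k),
      t = c(0, k * dt),
      x = c(0, cumsum(v_frames) * dt),
      v = c(v0, v_frames)
    )
  }
  out
}

#' One-dimensional elastic collision
#'
#' Post-collision velocities of two pucks colliding head-on on a line with
#' both momentum and kinetic energy conserved:
#' `uF = ((mF - mNF) vF + 2 mNF vNF) / (mF + mNF)` and symmetrically for
#' `uNF`. Friction is absent during the collision. Equal masses exchange
#' velocities.
#'
#' @param vF,vNF Pre-collision velocities of the known (`F`) and unknown
#'   (`NF`) puck, m/s. Vectorised.
#' @param mF,mNF Masses in kg (> 0).
#' @return A list with post-collision velocities `uF` and `uNF`.
#' @export
elastic_collision <- function(vF, vNF, mF, mNF) {
  if (any(!is.finite(mF)) || any(mF <= 0) || any(!is.finite(mNF)) || any(mNF <= 0)) {
    stop("masses must be finite and strictly positive", call. = FALSE)
  }
  total <- mF + mNF
  list(
    uF = ((mF - mNF) * vF + 2 * mNF * vNF) / total,
    uNF = ((mNF - mF) * vNF + 2 * mF * vF) / total
  )
}

#' Convert a simulated length to display pixels
#'
#' @param metres Length(s) in simulation space.
#' @param env An [env_params()] object supplying `pixels_per_metre`.
#' @return Length(s) in display pixels.
#' @examples
#' metres_to_pixels(0.05) # perceptual SD of 5 cm on the display
#' @export
metres_to_pixels <- function(metres, env = env_params()) {
  metres * env$pixels_per_metre
}
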