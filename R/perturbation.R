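#' Support-surface translation specification
#'
#' Horizontal platform translation used as a balance perturbation.  The
#' displacement follows a quintic smooth-step
#' \deqn{y(s) = d (10 s^3 - 15 s^4 + 6 s^5), \quad s = (t - onset)/duration,}
#' which for the standard 3 cm / 200 ms setting reduces to
#' \eqn{y(t) = 30 (t/200)^3 - 45 (t/200)^4 + 18 (t/200)^5} (cm, ms).  Velocity
#' and acceleration vanish at both ends of the translation window.
#'
#' @param direction_deg Translation direction in degrees; 0 = rightward,
#'   90 = forward (counterclockwise seen from above).
#' @param distance Translation distance, cm (default 3).
#' @param duration Translation duration, ms (default 200).
#' @param onset Perturbation onset, ms into the run (default 500).
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(direction_deg = 270, distance = 3,
                              duration = 200, onset = 500) {
  stopifnot(distance > 0, duration > 0, onset >= 0)
  direction_deg <- direction_deg %% 360
  structure(list(direction_deg = direction_deg, distance = distance,
                 duration = duration, onset = onset),
            class = "perturbation_spec")
}

#' @export
print.perturbation_spec <- function(x, ...) {
  cat(sprintf(
    "Support-surface translation: %g cm in %g ms toward %g deg (onset %g ms)\n",
    x$distance, x$duration, x$direction_deg, x$onset))
  invisible(x)
}

#' Platform displacement profile
#'
#' @param t Time, ms (vectorized).
#' @param spec A [perturbation_spec()].
#' @return Displacement along the translation direction, cm: 0 before onset,
#'   quintic smooth-step during the translation, constant at the full
#'   distance afterwards.
#' @export
translation_profile <- function(t, spec = perturbation_spec()) {
  s <- pmin(pmax((t - spec$onset) / spec$duration, 0), 1)
  spec$distance * (10 * s^3 - 15 * s^4 + 6 * s^5)
}

#' Platform velocity and acceleration
#'
#' Analytic first and second derivatives of [translation_profile()]; both are
#' exactly zero at onset and at the end of the translation.
#'
#' @inheritParams translation_profile
#' @return A list with `velocity` (cm/ms) and `acceleration` (cm/ms^2).
#' @export
translation_velocity_acceleration <- function(t, spec = perturbation_spec()) {
  s <- (t - spec$onset) / spec$duration
  inside <- s >= 0 & s <= 1
  s <- pmin(pmax(s, 0), 1)
  v <- spec$distance / spec$duration * (30 * s^2 - 60 * s^3 + 30 * s^4)
  a <- spec$distance / spec$duration^2 * (60 * s - 180 * s^2 + 120 * s^3)
  v[!inside] <- 0
  a[!inside] <- 0
  list(velocity = v, acceleration = a)
}

#' Direction unit components
#'
#' @param direction_deg Direction in degrees; 0 = rightward, 90 = forward.
#' @return Named vector `c(lateral, anterior)`: the rightward and forward
#'   unit components, which drive the frontal- and sagittal-plane plants.
#' @export
direction_components <- function(direction_deg) {
  th <- direction_deg * pi / 180
  c(lateral = cos(th), anterior = sin(th))
}

#' The 12 standard perturbation directions
#'
#' @return Numeric vector `seq(0, 330, by = 30)` (degrees).
#' @export
standard_directions <- function() seq(0, 330, by = 30)

# Internal: base-motion series for the integrator.
# Returns position/velocity (m) on the step grid (n_steps + 1) and
# acceleration (m/s^2) on the half-step grid (2 * n_steps + 1), scaled by a
# signed projection factor.
base_motion_series <- function(spec, dt, n_steps, projection = 1) {
  t_ms <- seq(0, n_steps * dt, by = dt) * 1000
  t_half_ms <- seq(0, n_steps * dt, by = dt / 2) * 1000
  pos <- translation_profile(t_ms, spec) * 0.01 * projection
  va <- translation_velocity_acceleration(t_ms, spec)
  vel <- va$velocity * 10 * projection             # cm/ms -> m/s
  acc_half <- translation_velocity_acceleration(t_half_ms, spec)$acceleration *
    1e4 * projection                               # cm/ms^2 -> m/s^2
  list(pos = pos, vel = vel, acc_half = acc_half)
}
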