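#' Multi-link plant configuration
#'
#' A planar serial chain of rigid links standing on a horizontally
#' translating platform.  Joint angles are relative; the absolute
#' orientation of link k (from vertical) is the cumulative sum of the joint
#' angles up to k.  Positive angles rotate the distal segment forward
#' (anterior) in a sagittal plant, or rightward in a frontal plant.  The
#' platform is kinematic: the feet are rigidly attached, and platform
#' acceleration enters the equations of motion as an inertial forcing term.
#'
#' @param links Data frame with one row per link and columns `mass` (kg),
#'   `length` (m), `com` (CoM offset from the proximal joint, m) and
#'   `inertia` (about the CoM, kg m^2).
#' @param joints Character vector of joint labels (one per link).
#' @param plane `"sagittal"` or `"frontal"`.
#' @param gravity Gravitational acceleration, m/s^2.
#' @param initial_pose Per-joint initial angles, rad.
#' @param joint_limits Two-column matrix of per-joint angle limits, rad
#'   (used to flag constraint events, not enforced).
#' @param joint_damping Per-joint passive viscous damping, N m s/rad.
#' @param fall_height_fraction The fall threshold as a fraction of the
#'   initial CoM height (default 0.9); `fall_height` may instead give an
#'   absolute threshold in m for full-anthropometry plants.
#' @param fall_height Optional absolute fall threshold, m (overrides the
#'   fraction when non-`NULL`).
#' @return An object of class `plant_config`.
#' @export
plant_config <- function(links, joints, plane = c("sagittal", "frontal"),
                         gravity = 9.80665, initial_pose = NULL,
                         joint_limits = NULL, joint_damping = NULL,
                         fall_height_fraction = 0.9, fall_height = NULL) {
  plane <- match.arg(plane)
  links <- as.data.frame(links)
  stopifnot(all(c("mass", "length", "com", "inertia") %in% names(links)),
            all(links$mass > 0), all(links$length > 0),
            all(links$inertia > 0), all(links$com > 0),
            all(links$com <= links$length),
            length(joints) == nrow(links),
            fall_height_fraction > 0, fall_height_fraction < 1)
  n <- nrow(links)
  if (is.null(initial_pose)) initial_pose <- rep(0, n)
  if (is.null(joint_limits))
    joint_limits <- cbind(rep(-pi / 2, n), rep(pi / 2, n))
  if (is.null(joint_damping)) joint_damping <- rep(0, n)
  stopifnot(length(initial_pose) == n, nrow(joint_limits) == n,
            length(joint_damping) == n, all(joint_damping >= 0))
  structure(list(links = links, joints = joints, plane = plane,
                 gravity = gravity, initial_pose = initial_pose,
                 joint_limits = joint_limits, joint_damping = joint_damping,
                 fall_height_fraction = fall_height_fraction,
                 fall_height = fall_height),
            class = "plant_config")
}

#' @export
print.plant_config <- function(x, ...) {
  cat(sprintf("%s-plane plant: %d links, total mass %.1f kg\n",
              x$plane, nrow(x$links), sum(x$links$mass)))
  for (i in seq_len(nrow(x$links)))
    cat(sprintf("  %-14s m = %5.1f kg  l = %.3f m  com = %.3f m  I = %.4g\n",
                x$joints[i], x$links$mass[i], x$links$length[i],
                x$links$com[i], x$links$inertia[i]))
  cat(sprintf("  upright CoM height: %.3f m; fall threshold: %s\n",
              com_height(x, rep(0, nrow(x$links))),
              if (is.null(x$fall_height))
                sprintf("%.0f%% of initial CoM height",
                        100 * x$fall_height_fraction)
              else sprintf("%.3f m", x$fall_height)))
  invisible(x)
}

# Internal: chain coefficients a[k, i] (distance factors), masses
chain_coefs <- function(config) {
  l <- config$links$length
  d <- config$links$com
  m <- config$links$mass
  n <- length(l)
  A <- matrix(0, n, n)
  for (k in seq_len(n)) {
    if (k > 1) A[k, seq_len(k - 1)] <- l[seq_len(k - 1)]
    A[k, k] <- d[k]
  }
  list(A = A, m = m, I = config$links$inertia, n = n)
}

#' Joint torques from muscle forces
#'
#' \eqn{\tau_j = \sum_i F_i \, ma_{ij}}.
#'
#' @param forces Per-muscle forces, N.
#' @param muscles A [muscle_set()] (for the moment arms).
#' @return Per-joint torques, N m.
#' @export
joint_torques_from_muscles <- function(forces, muscles) {
  mm <- muscle_matrices(muscles)
  if (length(forces) != nrow(mm$ma))
    stop("force count must equal muscle count")
  as.numeric(crossprod(mm$ma, forces))
}

#' Forward dynamics of the chain
#'
#' Joint accelerations of the serial chain on a horizontally accelerating
#' base, from \eqn{M(\theta)\ddot\theta + C(\theta,\dot\theta) + G(\theta) =
#' \tau + \tau_{base}}.  Computed in absolute-angle coordinates and mapped
#' back to relative joint coordinates.
#'
#' @param config A [plant_config()].
#' @param theta,theta_dot Joint angles (rad) and velocities (rad/s).
#' @param joint_torques Per-joint applied torques, N m (muscle torques;
#'   passive joint damping is added internally).
#' @param base_acc Platform horizontal acceleration, m/s^2.
#' @return Joint angular accelerations, rad/s^2.
#' @export
plant_dynamics <- function(config, theta, theta_dot, joint_torques,
                           base_acc = 0) {
  cc <- chain_coefs(config)
  n <- cc$n
  phi <- cumsum(theta)
  phid <- cumsum(theta_dot)
  tau <- joint_torques - config$joint_damping * theta_dot
  # generalized joint torque in absolute coordinates: tau_i - tau_{i+1}
  Q <- tau - c(tau[-1], 0)
  M <- matrix(0, n, n)
  Cv <- numeric(n)
  mu <- numeric(n)
  for (i in seq_len(n)) {
    mu[i] <- sum(cc$m[i:n] * cc$A[i:n, i])
    for (j in seq_len(n)) {
      kk <- max(i, j):n
      S <- sum(cc$m[kk] * cc$A[kk, i] * cc$A[kk, j])
      M[i, j] <- S * cos(phi[i] - phi[j]) + if (i == j) cc$I[i] else 0
      Cv[i] <- Cv[i] + S * sin(phi[i] - phi[j]) * phid[j]^2
    }
  }
  rhs <- Q + config$gravity * mu * sin(phi) - mu * cos(phi) * base_acc - Cv
  phidd <- tryCatch(solve(M, rhs),
                    error = function(e) stop("singular mass matrix"))
  diff(c(0, phidd))
}

#' Whole-body centre-of-mass height
#'
#' @param config A [plant_config()].
#' @param theta Joint angles, rad.
#' @return Height of the whole-body CoM above the platform surface, m.
#' @export
com_height <- function(config, theta) {
  cc <- chain_coefs(config)
  phi <- cumsum(theta)
  z <- as.numeric(cc$A %*% cos(phi))
  sum(cc$m * z) / sum(cc$m)
}

# Internal: total mechanical energy of the passive chain (base at rest)
plant_energy <- function(config, theta, theta_dot) {
  cc <- chain_coefs(config)
  phi <- cumsum(theta)
  phid <- cumsum(theta_dot)
  n <- cc$n
  Tk <- 0
  for (k in seq_len(n)) {
    vx <- sum(cc$A[k, ] * cos(phi) * phid)
    vz <- -sum(cc$A[k, ] * sin(phi) * phid)
    Tk <- Tk + 0.5 * cc$m[k] * (vx^2 + vz^2) + 0.5 * cc$I[k] * phid[k]^2
  }
  V <- config$gravity * sum(cc$m * as.numeric(cc$A %*% cos(phi)))
  Tk + V
}

# Internal: resolved fall threshold (absolute, m) for a config
fall_threshold <- function(config) {
  if (!is.null(config$fall_height)) return(config$fall_height)
  config$fall_height_fraction * com_height(config, config$initial_pose)
}

#' One passive integration step
#'
#' Advances the plant state one fixed RK4 step under externally supplied
#' joint torques and base acceleration (both held constant over the step).
#' The closed-loop simulator [simulate_stance()] performs the same update
#' with muscle torques recomputed at each Runge-Kutta stage.
#'
#' @inheritParams plant_dynamics
#' @param dt Step, s (> 0).
#' @return List with updated `theta` and `theta_dot`.
#' @export
plant_step <- function(config, theta, theta_dot, joint_torques = NULL,
                       base_acc = 0, dt = 0.001) {
  stopifnot(dt > 0)
  n <- nrow(config$links)
  if (is.null(joint_torques)) joint_torques <- rep(0, n)
  f <- function(th, thd)
    list(dth = thd,
         dthd = plant_dynamics(config, th, thd, joint_torques, base_acc))
  k1 <- f(theta, theta_dot)
  k2 <- f(theta + dt / 2 * k1$dth, theta_dot + dt / 2 * k1$dthd)
  k3 <- f(theta + dt / 2 * k2$dth, theta_dot + dt / 2 * k2$dthd)
  k4 <- f(theta + dt * k3$dth, theta_dot + dt * k3$dthd)
  th <- theta + dt / 6 * (k1$dth + 2 * k2$dth + 2 * k3$dth + k4$dth)
  thd <- theta_dot + dt / 6 * (k1$dthd + 2 * k2$dthd + 2 * k3$dthd + k4$dthd)
  if (any(!is.finite(c(th, thd)))) stop("divergence: non-finite plant state")
  list(theta = th, theta_dot = thd)
}

#' Detect a fall in a trajectory
#'
#' Scans the CoM-height series; a fall is declared at the first sample whose
#' CoM height drops below the threshold.
#'
#' @param traj A `stance_trajectory` (or any list with `time` in s and
#'   `com_height` in m).
#' @param threshold Fall threshold, m.
#' @return `T_fall` in ms: the full horizon if the CoM height never drops
#'   below the threshold, else the time of the first crossing.
#' @export
detect_fall <- function(traj, threshold) {
  h <- traj$com_height
  if (!length(h)) stop("empty trajectory")
  below <- which(h < threshold)
  if (!length(below)) return(traj$time[length(h)] * 1000)
  traj$time[below[1]] * 1000
}
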