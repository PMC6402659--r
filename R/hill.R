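#' Hill-type muscle curve constants
#'
#' Bundles the dimensionless shape constants of the three normalized curves
#' used by the Hill-type actuator: the active force-length curve
#' \eqn{f_L(\tilde l) = \exp(-(\tilde l - 1)^2 / \gamma)}, the force-velocity
#' curve \eqn{f_V(\tilde v)} (hyperbolic concentric branch, slope-continuous
#' eccentric branch saturating at `F_len`), and the passive exponential
#' force-length curve \eqn{f_{PE}(\tilde l)} which is zero at or below the
#' optimal fiber length and reaches one at strain `eps0_PE`.
#'
#' @param gamma_fl Width of the active force-length Gaussian (> 0).
#' @param A_f Force-velocity shape constant (0 < A_f < 1).
#' @param F_len Eccentric force plateau (> 1).
#' @param k_PE Passive exponential shape constant (> 0).
#' @param eps0_PE Passive strain at which the normalized passive force
#'   equals one (> 0).
#' @return An object of class `hill_curves`.
#' @examples
#' cv <- hill_curves()
#' active_force_length(1, cv)      # 1 at the optimum
#' force_velocity(0, cv)           # 1 under isometric conditions
#' passive_force_length(1.6, cv)   # 1 at optimal length + eps0_PE
#' @export
hill_curves <- function(gamma_fl = 0.45, A_f = 0.25, F_len = 1.4,
                        k_PE = 4, eps0_PE = 0.6) {
  stopifnot(gamma_fl > 0, A_f > 0, A_f < 1, F_len > 1, k_PE > 0, eps0_PE > 0)
  structure(list(gamma_fl = gamma_fl, A_f = A_f, F_len = F_len,
                 k_PE = k_PE, eps0_PE = eps0_PE),
            class = "hill_curves")
}

#' @export
print.hill_curves <- function(x, ...) {
  cat("Hill-type curve constants:\n")
  cat(sprintf("  f_L   Gaussian width gamma_fl = %.3g\n", x$gamma_fl))
  cat(sprintf("  f_V   A_f = %.3g, eccentric plateau F_len = %.3g\n",
              x$A_f, x$F_len))
  cat(sprintf("  f_PE  k_PE = %.3g, eps0_PE = %.3g\n", x$k_PE, x$eps0_PE))
  invisible(x)
}

#' Active force-length curve
#'
#' @param l_norm Normalized fiber length (>= 0); 1 is the optimal length.
#' @param curves A [hill_curves()] object.
#' @return Dimensionless force scaler in (0, 1], maximal at `l_norm = 1`.
#' @export
active_force_length <- function(l_norm, curves = hill_curves()) {
  if (any(l_norm < 0)) stop("l_norm must be non-negative")
  exp(-(l_norm - 1)^2 / curves$gamma_fl)
}

#' Force-velocity curve
#'
#' Concentric branch \eqn{(1 + v)/(1 - v/A_f)} for \eqn{-1 < v \le 0},
#' zero at or below the maximum shortening velocity \eqn{v = -1}, and an
#' eccentric branch \eqn{(F_{len} v + c)/(v + c)} with
#' \eqn{c = (F_{len} - 1)/(1 + 1/A_f)} chosen so the slope is continuous at
#' \eqn{v = 0}.  Monotone non-decreasing, saturating at `F_len`.
#'
#' @param v_norm Normalized fiber velocity (negative = shortening).
#' @param curves A [hill_curves()] object.
#' @return Dimensionless force scaler in [0, F_len).
#' @export
force_velocity <- function(v_norm, curves = hill_curves()) {
  A <- curves$A_f
  Fl <- curves$F_len
  cc <- (Fl - 1) / (1 + 1 / A)
  ifelse(v_norm <= -1, 0,
         ifelse(v_norm <= 0,
                (1 + v_norm) / (1 - v_norm / A),
                (Fl * v_norm + cc) / (v_norm + cc)))
}

#' Passive force-length curve
#'
#' Zero at or below the optimal length; exponential
#' \eqn{(\exp(k_{PE}(\tilde l - 1)/\epsilon_0) - 1)/(\exp(k_{PE}) - 1)}
#' above it, reaching one at \eqn{\tilde l = 1 + \epsilon_0}.
#'
#' @inheritParams active_force_length
#' @return Dimensionless force scaler (>= 0).
#' @export
passive_force_length <- function(l_norm, curves = hill_curves()) {
  if (any(l_norm < 0)) stop("l_norm must be non-negative")
  out <- numeric(length(l_norm))
  up <- l_norm > 1
  out[up] <- (exp(curves$k_PE * (l_norm[up] - 1) / curves$eps0_PE) - 1) /
    (exp(curves$k_PE) - 1)
  out
}

#' Muscle-tendon actuator parameters
#'
#' Constants of one Hill-type muscle-tendon actuator together with its path
#' geometry.  Paths are affine: the musculotendon length is
#' `L_ref - sum(moment_arms * theta)`, so each moment arm is exactly the
#' negative derivative of length with respect to its joint angle, and its
#' sign encodes flexor/extensor action.
#'
#' @param name Muscle identifier.
#' @param F0 Maximum isometric force, N.
#' @param L_opt Optimal fiber length, m.
#' @param L_slack Constant series slack length, m (rigid tendon).
#' @param L_ref Musculotendon length at zero joint angles, m.
#' @param V_max Maximum lengthening-velocity limit, m/s.
#' @param moment_arms Named or plain numeric vector of per-joint constant
#'   moment arms, m; at least one must be nonzero.
#' @param group Muscle-group label used for gain sharing.
#' @param t_act Activation time constant, s (default 0.010).
#' @param t_deact Deactivation time constant, s (default 0.040).
#' @return An object of class `muscle`.
#' @export
muscle <- function(name, F0, L_opt, L_slack, L_ref, V_max, moment_arms,
                   group, t_act = 0.010, t_deact = 0.040) {
  stopifnot(F0 > 0, L_opt > 0, L_slack >= 0, L_ref > 0, V_max > 0,
            t_act > 0, t_deact > 0)
  if (all(moment_arms == 0)) stop("at least one moment arm must be nonzero")
  structure(list(name = name, F0 = F0, L_opt = L_opt, L_slack = L_slack,
                 L_ref = L_ref, V_max = V_max,
                 moment_arms = as.numeric(moment_arms),
                 group = group, t_act = t_act, t_deact = t_deact),
            class = "muscle")
}

#' Bundle muscles into a muscle set
#'
#' @param ... `muscle` objects (or a single list of them).
#' @return An object of class `muscle_set`: a list of muscles with
#'   consistent moment-arm dimensions.
#' @export
muscle_set <- function(...) {
  ms <- list(...)
  if (length(ms) == 1L && !inherits(ms[[1]], "muscle")) ms <- ms[[1]]
  stopifnot(length(ms) > 0, all(vapply(ms, inherits, TRUE, "muscle")))
  nj <- unique(vapply(ms, function(m) length(m$moment_arms), 1L))
  if (length(nj) != 1L)
    stop("all muscles must have moment arms for the same joints")
  names(ms) <- vapply(ms, function(m) m$name, "")
  structure(ms, class = "muscle_set")
}

#' @export
print.muscle_set <- function(x, ...) {
  cat(sprintf("Muscle set: %d muscles, %d joints\n",
              length(x), length(x[[1]]$moment_arms)))
  for (m in x)
    cat(sprintf("  %-16s F0 = %6.0f N  group = %-18s ma = [%s] m\n",
                m$name, m$F0, m$group,
                paste(sprintf("%+.3f", m$moment_arms), collapse = ", ")))
  invisible(x)
}

# Internal: matrix of moment arms (n_muscle x n_joint) and parameter vectors
muscle_matrices <- function(muscles) {
  ma <- do.call(rbind, lapply(muscles, function(m) m$moment_arms))
  list(
    ma = ma,
    F0 = vapply(muscles, function(m) m$F0, 1),
    L_opt = vapply(muscles, function(m) m$L_opt, 1),
    L_slack = vapply(muscles, function(m) m$L_slack, 1),
    L_ref = vapply(muscles, function(m) m$L_ref, 1),
    V_max = vapply(muscles, function(m) m$V_max, 1),
    t_act = vapply(muscles, function(m) m$t_act, 1),
    t_deact = vapply(muscles, function(m) m$t_deact, 1),
    group = vapply(muscles, function(m) m$group, ""),
    name = vapply(muscles, function(m) m$name, "")
  )
}

#' Hill-type muscle force
#'
#' \eqn{F = F_0 (a f_L(\tilde l) f_V(\tilde v) + f_{PE}(\tilde l))}.
#'
#' @param params A [muscle()] object (only `F0` is used here).
#' @param a Activation in \[0, 1\].
#' @param l_norm,v_norm Normalized fiber length and velocity.
#' @param curves A [hill_curves()] object.
#' @return Force in N (>= 0).
#' @export
muscle_force <- function(params, a, l_norm, v_norm, curves = hill_curves()) {
  if (any(a < 0) || any(a > 1)) stop("activation must lie in [0, 1]")
  params$F0 * (a * active_force_length(l_norm, curves) *
                 force_velocity(v_norm, curves) +
                 passive_force_length(l_norm, curves))
}

#' Musculotendon kinematics from joint state
#'
#' Affine path model: `L_MT = L_ref - sum(ma * theta)`,
#' `Ldot_MT = -sum(ma * theta_dot)`, with normalized fiber length
#' `(L_MT - L_slack)/L_opt` (rigid tendon) and normalized velocity
#' `Ldot_MT / V_max`.
#'
#' @param params A [muscle()] object.
#' @param joint_angles Joint angles, rad (same length as the moment arms).
#' @param joint_velocities Joint angular velocities, rad/s.
#' @return A list with `L_MT`, `Ldot_MT` (m, m/s) and `l_norm`, `v_norm`.
#' @export
musculotendon_kinematics <- function(params, joint_angles, joint_velocities) {
  ma <- params$moment_arms
  if (length(joint_angles) != length(ma) ||
      length(joint_velocities) != length(ma))
    stop("joint state length must match the moment-arm vector")
  L <- params$L_ref - sum(ma * joint_angles)
  if (L <= 0) stop("degenerate geometry: musculotendon length <= 0")
  Ld <- -sum(ma * joint_velocities)
  list(L_MT = L, Ldot_MT = Ld,
       l_norm = (L - params$L_slack) / params$L_opt,
       v_norm = Ld / params$V_max)
}
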