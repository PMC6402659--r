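#' Closed-loop standing-balance simulation
#'
#' Runs the full loop at a fixed step: muscle kinematics, delayed PD
#' feedback, total control, transmission-delayed first-order activation
#' dynamics, Hill-type muscle forces, joint torques, and plant dynamics on
#' the translating platform, with the classical RK4 scheme on the coupled
#' state.  Delayed signals are stored on the integrator grid and held
#' constant across Runge-Kutta stages.  The run terminates early when the
#' CoM height drops below the fall threshold ("fell") or the state becomes
#' non-finite ("diverged"); the partial trajectory is returned.
#'
#' @param config A [plant_config()].
#' @param muscles A [muscle_set()].
#' @param controller A [controller_params()]; when its `L0_MT` is `NULL`
#'   the target lengths are computed from the configured initial pose.
#' @param perturbation A [perturbation_spec()] or `NULL` for an unperturbed
#'   run.  Its direction is projected onto the plant's plane (anterior
#'   component for sagittal, lateral for frontal).
#' @param T_simu Simulation horizon, ms.
#' @param dt Integrator step, s (<= 0.001).
#' @param curves A [hill_curves()] object.
#' @param a0 Initial activations (defaults to the clipped feed-forward
#'   vector, the closed-loop rest state at the target pose).
#' @param engine `"cpp"` (compiled core, default) or `"R"` (reference
#'   implementation of the identical scheme, for cross-checking).
#' @return An object of class `stance_trajectory`.
#' @export
simulate_stance <- function(config, muscles, controller, perturbation = NULL,
                            T_simu = 5000, dt = 0.001,
                            curves = hill_curves(), a0 = NULL,
                            engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  stopifnot(inherits(config, "plant_config"), inherits(muscles, "muscle_set"),
            inherits(controller, "controller_params"), dt > 0, dt <= 0.001,
            T_simu > 0)
  mm <- muscle_matrices(muscles)
  nj <- nrow(config$links)
  nm <- length(muscles)
  if (ncol(mm$ma) != nj)
    stop("muscle moment arms and plant joints are inconsistent")
  if (length(controller$u_ff) != nm)
    stop("controller u_ff length must equal muscle count")

  theta0 <- config$initial_pose
  L0 <- controller$L0_MT
  if (is.null(L0)) L0 <- as.numeric(mm$L_ref - mm$ma %*% theta0)
  if (any(L0 <= 0)) stop("degenerate geometry: non-positive target length")

  n_steps <- as.integer(round(T_simu / 1000 / dt))
  proj <- if (is.null(perturbation)) 0 else {
    dc <- direction_components(perturbation$direction_deg)
    if (config$plane == "sagittal") unname(dc["anterior"])
    else unname(dc["lateral"])
  }
  base <- if (is.null(perturbation) || proj == 0) {
    list(pos = numeric(n_steps + 1), vel = numeric(n_steps + 1),
         acc_half = numeric(2 * n_steps + 1))
  } else base_motion_series(perturbation, dt, n_steps, proj)

  gains <- expand_gains(controller)
  if (is.null(a0))
    a0 <- pmin(pmax(controller$u_ff, controller$u_clip[1]),
               controller$u_clip[2])
  fall_h <- fall_threshold(config)
  fb_steps <- as.integer(round(controller$tau_fb / dt))
  trans_steps <- as.integer(round(controller$tau_trans / dt))

  core_args <- list(config$links$mass, config$links$length,
                    config$links$com, config$links$inertia,
                    config$joint_damping, config$gravity,
                    mm$ma, mm$F0, mm$L_opt, mm$L_slack, mm$L_ref, mm$V_max,
                    mm$t_act, mm$t_deact,
                    curves$gamma_fl, curves$A_f, curves$F_len, curves$k_PE,
                    curves$eps0_PE,
                    controller$u_ff, gains$kp, gains$kd, L0,
                    controller$Ldot0_MT,
                    controller$u_clip[1], controller$u_clip[2],
                    fb_steps, trans_steps,
                    theta0, rep(0, nj), a0,
                    base$acc_half, dt, n_steps, fall_h)
  res <- if (engine == "cpp") do.call(.simulate_core, core_args)
  else do.call(simulate_core_r, core_args)

  keep <- seq_len(res$last_step + 1L)
  traj <- structure(list(
    time = (keep - 1L) * dt,
    theta = res$theta[keep, , drop = FALSE],
    theta_dot = res$theta_dot[keep, , drop = FALSE],
    activations = res$a[keep, , drop = FALSE],
    controls = res$u[keep, , drop = FALSE],
    controls_raw = res$u_raw[keep, , drop = FALSE],
    L_MT = res$L_MT[keep, , drop = FALSE],
    Ldot_MT = res$Ldot_MT[keep, , drop = FALSE],
    com_height = res$com_height[keep],
    base_pos = base$pos[keep],
    base_vel = base$vel[keep],
    t_fall = res$t_fall_ms,
    stood = res$stood,
    status = res$status,
    dt = dt, T_simu = T_simu,
    fall_threshold = fall_h,
    joints = config$joints,
    muscles = mm$name,
    uff_norm_sq = sum(controller$u_ff^2),
    config = config, controller = controller,
    perturbation = perturbation,
    L0_MT = L0
  ), class = "stance_trajectory")
  colnames(traj$theta) <- colnames(traj$theta_dot) <- config$joints
  colnames(traj$activations) <- colnames(traj$controls) <- mm$name
  colnames(traj$controls_raw) <- mm$name
  colnames(traj$L_MT) <- colnames(traj$Ldot_MT) <- mm$name
  traj
}

# R reference implementation of the compiled core: identical scheme,
# stage-for-stage, used in tests as an independent route.
simulate_core_r <- function(link_m, link_l, link_d, link_I, joint_damping, g,
                            ma, F0, L_opt, L_slack, L_ref, V_max,
                            t_act, t_deact,
                            gamma_fl, A_f, F_len, k_PE, eps0_PE,
                            u_ff, kp, kd, L0, Ldot0, clip_lo, clip_hi,
                            fb_steps, trans_steps,
                            theta0, thetadot0, a0,
                            base_acc_half, dt, n_steps, fall_h) {
  n <- length(link_m); nm <- length(F0)
  cv <- hill_curves(gamma_fl, A_f, F_len, k_PE, eps0_PE)
  A <- matrix(0, n, n)
  for (k in seq_len(n)) {
    if (k > 1) A[k, seq_len(k - 1)] <- link_l[seq_len(k - 1)]
    A[k, k] <- link_d[k]
  }
  mu <- vapply(seq_len(n), function(i) sum(link_m[i:n] * A[i:n, i]), 1)
  total_m <- sum(link_m)

  com_h <- function(th) {
    phi <- cumsum(th)
    sum(link_m * as.numeric(A %*% cos(phi))) / total_m
  }
  accel <- function(th, thd, tau, bacc) {
    phi <- cumsum(th); phid <- cumsum(thd)
    Q <- tau - c(tau[-1], 0)
    M <- matrix(0, n, n); Cv <- numeric(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      kk <- max(i, j):n
      S <- sum(link_m[kk] * A[kk, i] * A[kk, j])
      M[i, j] <- S * cos(phi[i] - phi[j]) + if (i == j) link_I[i] else 0
      Cv[i] <- Cv[i] + S * sin(phi[i] - phi[j]) * phid[j]^2
    }
    rhs <- Q + g * mu * sin(phi) - mu * cos(phi) * bacc - Cv
    diff(c(0, solve(M, rhs)))
  }
  dstate <- function(th, thd, a, u_del, bacc) {
    L <- L_ref - as.numeric(ma %*% th)
    Ld <- -as.numeric(ma %*% thd)
    l <- (L - L_slack) / L_opt
    v <- Ld / V_max
    ac <- pmin(pmax(a, 0), 1)
    F <- F0 * (ac * active_force_length(l, cv) * force_velocity(v, cv) +
                 passive_force_length(l, cv))
    tau <- as.numeric(crossprod(ma, F)) - joint_damping * thd
    list(dth = thd, dthd = accel(th, thd, tau, bacc),
         da = (u_del - a) /
           activation_time_constant(ac, u_del, t_act, t_deact))
  }

  N <- n_steps
  theta_out <- thetad_out <- matrix(NA_real_, N + 1, n)
  a_out <- u_out <- uraw_out <- L_out <- Ld_out <- matrix(NA_real_, N + 1, nm)
  h_out <- rep(NA_real_, N + 1)
  u_hist <- matrix(NA_real_, N + 1, nm)

  th <- theta0; thd <- thetadot0; a <- a0
  status <- "completed"; t_fall_ms <- N * dt * 1000; stood <- TRUE; last <- N

  for (k in 0:N) {
    if (any(!is.finite(c(th, thd)))) {
      status <- "diverged"; stood <- FALSE; t_fall_ms <- k * dt * 1000
      last <- max(k - 1, 0); break
    }
    theta_out[k + 1, ] <- th; thetad_out[k + 1, ] <- thd
    L <- L_ref - as.numeric(ma %*% th)
    Ld <- -as.numeric(ma %*% thd)
    L_out[k + 1, ] <- L; Ld_out[k + 1, ] <- Ld; a_out[k + 1, ] <- a
    h <- com_h(th); h_out[k + 1] <- h

    kfb <- max(k - fb_steps, 0)
    ufb <- kp * (L_out[kfb + 1, ] - L0) / L0 +
      kd * (Ld_out[kfb + 1, ] - Ldot0) / V_max
    raw <- u_ff + ufb
    uc <- pmin(pmax(raw, clip_lo), clip_hi)
    u_hist[k + 1, ] <- uc; u_out[k + 1, ] <- uc; uraw_out[k + 1, ] <- raw

    if (h < fall_h) {
      status <- "fell"; stood <- FALSE; t_fall_ms <- k * dt * 1000
      last <- k; break
    }
    if (k == N) break

    u_del <- u_hist[max(k - trans_steps, 0) + 1, ]
    b1 <- base_acc_half[2 * k + 1]
    b2 <- base_acc_half[2 * k + 2]
    b4 <- base_acc_half[2 * k + 3]
    s1 <- dstate(th, thd, a, u_del, b1)
    s2 <- dstate(th + dt / 2 * s1$dth, thd + dt / 2 * s1$dthd,
                 a + dt / 2 * s1$da, u_del, b2)
    s3 <- dstate(th + dt / 2 * s2$dth, thd + dt / 2 * s2$dthd,
                 a + dt / 2 * s2$da, u_del, b2)
    s4 <- dstate(th + dt * s3$dth, thd + dt * s3$dthd,
                 a + dt * s3$da, u_del, b4)
    th <- th + dt / 6 * (s1$dth + 2 * s2$dth + 2 * s3$dth + s4$dth)
    thd <- thd + dt / 6 * (s1$dthd + 2 * s2$dthd + 2 * s3$dthd + s4$dthd)
    a <- pmin(pmax(a + dt / 6 * (s1$da + 2 * s2$da + 2 * s3$da + s4$da),
                   0), 1)
  }
  list(theta = theta_out, theta_dot = thetad_out, a = a_out, u = u_out,
       u_raw = uraw_out, L_MT = L_out, Ldot_MT = Ld_out,
       com_height = h_out, t_fall_ms = t_fall_ms, stood = stood,
       status = status, last_step = last)
}

#' @export
print.stance_trajectory <- function(x, ...) {
  cat(sprintf("Stance simulation (%s plant, %d muscles): %s\n",
              x$config$plane, length(x$muscles), x$status))
  cat(sprintf("  horizon %g ms, dt %g ms; T_fall = %g ms (threshold %.3f m)\n",
              x$T_simu, 1000 * x$dt, x$t_fall, x$fall_threshold))
  cat(sprintf("  ||u_ff||^2 = %.4g; final CoM height %.3f m\n",
              x$uff_norm_sq, x$com_height[length(x$com_height)]))
  if (!is.null(x$perturbation))
    cat(sprintf("  perturbation: %g cm toward %g deg at %g ms\n",
                x$perturbation$distance, x$perturbation$direction_deg,
                x$perturbation$onset))
  invisible(x)
}

#' @export
as.data.frame.stance_trajectory <- function(x, ...) {
  df <- data.frame(time = x$time, base_pos = x$base_pos,
                   com_height = x$com_height)
  for (j in seq_along(x$joints))
    df[[paste0("theta_", x$joints[j])]] <- x$theta[, j]
  for (i in seq_along(x$muscles)) {
    df[[paste0("a_", x$muscles[i])]] <- x$activations[, i]
    df[[paste0("u_", x$muscles[i])]] <- x$controls[, i]
    df[[paste0("L_", x$muscles[i])]] <- x$L_MT[, i]
  }
  df
}

#' @export
plot.stance_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$time, x$com_height, type = "l", xlab = "time [s]",
                 ylab = "CoM height [m]", main = "")
  graphics::abline(h = x$fall_threshold, lty = 2)
  graphics::matplot(x$time, x$theta * 180 / pi, type = "l", lty = 1,
                    xlab = "time [s]", ylab = "joint angle [deg]")
  graphics::legend("topleft", legend = x$joints, col = seq_along(x$joints),
                   lty = 1, bty = "n", cex = 0.8)
  graphics::matplot(x$time, x$activations, type = "l", lty = 1,
                    xlab = "time [s]", ylab = "activation")
  graphics::legend("topleft", legend = x$muscles,
                   col = seq_along(x$muscles), lty = 1, bty = "n", cex = 0.7)
  invisible(x)
}
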