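#' Neural-controller parameters
#'
#' Parameters of the feed-forward + delayed-PD-feedback controller.  The
#' total per-muscle control is \eqn{u(t) = u_{ff} + u_{fb}(t)}, clipped to
#' `u_clip`, where the feedback component uses musculotendon length and
#' lengthening velocity delayed by `tau_fb`:
#' \deqn{u_{fb,i}(t) = k_{p,i} \frac{L^{MT}_i(t-\tau_{fb}) - L^{MT}_{i,0}}
#'   {L^{MT}_{i,0}} + k_{d,i} \frac{\dot L^{MT}_i(t-\tau_{fb}) - 0}{V_{i,max}}.}
#' Controls pass through first-order activation dynamics after a further
#' transmission delay `tau_trans`.  Muscles mapped to the same group share
#' identical (k_p, k_d).
#'
#' @param u_ff Per-muscle constant feed-forward activation, each in \[0, 1\].
#' @param k_p,k_d Named per-group proportional and derivative gains (>= 0);
#'   names must cover every group in `group_map`.
#' @param group_map Character vector mapping each muscle to its group.
#' @param tau_fb Feedback delay, s (default 0.040).
#' @param tau_trans Transmission delay, s (default 0.040).
#' @param L0_MT Per-muscle target musculotendon length, m (computed from the
#'   initial pose when `NULL`; see [simulate_stance()]).
#' @param u_clip Lower/upper control bounds (default `c(0.001, 1)`).
#' @return An object of class `controller_params`.
#' @export
controller_params <- function(u_ff, k_p, k_d, group_map,
                              tau_fb = 0.040, tau_trans = 0.040,
                              L0_MT = NULL, u_clip = c(0.001, 1)) {
  stopifnot(all(u_ff >= 0), all(u_ff <= 1), all(k_p >= 0), all(k_d >= 0),
            tau_fb >= 0, tau_trans >= 0, length(u_clip) == 2,
            u_clip[1] < u_clip[2])
  if (length(u_ff) != length(group_map))
    stop("u_ff and group_map must have one entry per muscle")
  miss <- setdiff(unique(group_map), names(k_p))
  if (length(miss))
    stop("groups without gains: ", paste(miss, collapse = ", "))
  miss <- setdiff(unique(group_map), names(k_d))
  if (length(miss))
    stop("groups without derivative gains: ", paste(miss, collapse = ", "))
  structure(list(u_ff = u_ff, k_p = k_p, k_d = k_d, group_map = group_map,
                 tau_fb = tau_fb, tau_trans = tau_trans,
                 L0_MT = L0_MT, Ldot0_MT = 0, u_clip = u_clip),
            class = "controller_params")
}

#' @export
print.controller_params <- function(x, ...) {
  cat(sprintf("Neural controller: %d muscles, %d gain groups\n",
              length(x$u_ff), length(unique(x$group_map))))
  cat(sprintf("  ||u_ff||^2 = %.4g; tau_fb = %g ms, tau_trans = %g ms\n",
              sum(x$u_ff^2), 1000 * x$tau_fb, 1000 * x$tau_trans))
  g <- unique(x$group_map)
  for (gg in g)
    cat(sprintf("  %-20s k_p = %.4g  k_d = %.4g\n", gg, x$k_p[[gg]],
                x$k_d[[gg]]))
  invisible(x)
}

# Internal: expand per-group gains to per-muscle vectors
expand_gains <- function(params) {
  list(kp = unname(params$k_p[params$group_map]),
       kd = unname(params$k_d[params$group_map]))
}

#' Delayed PD feedback control for one muscle
#'
#' @param L_delayed Musculotendon length at `t - tau_fb`, m.
#' @param Ldot_delayed Lengthening velocity at `t - tau_fb`, m/s.
#' @param params A [controller_params()] object.
#' @param muscle A [muscle()] object (for `V_max`).
#' @param muscle_index Index of the muscle in the controller (for its gain
#'   group and target length).
#' @return The feedback component `u_fb` (may be negative; clipping happens
#'   in [total_control()]).
#' @export
feedback_control <- function(L_delayed, Ldot_delayed, params, muscle,
                             muscle_index = 1L) {
  L0 <- params$L0_MT[muscle_index]
  if (is.null(L0) || !is.finite(L0) || L0 <= 0)
    stop("invalid target length L0_MT")
  if (muscle$V_max <= 0) stop("invalid V_max")
  g <- params$group_map[muscle_index]
  params$k_p[[g]] * (L_delayed - L0) / L0 +
    params$k_d[[g]] * (Ldot_delayed - params$Ldot0_MT) / muscle$V_max
}

#' Total control
#'
#' Sums the feed-forward and feedback components and clips to the configured
#' bounds.
#'
#' @param u_ff,u_fb Feed-forward and feedback components (vectorized).
#' @param u_clip Length-2 lower/upper bounds.
#' @return A list with `u` (clipped) and `u_raw` (unclipped sum).
#' @export
total_control <- function(u_ff, u_fb, u_clip = c(0.001, 1)) {
  raw <- u_ff + u_fb
  list(u = pmin(pmax(raw, u_clip[1]), u_clip[2]), u_raw = raw)
}

#' State-dependent activation time constant
#'
#' \eqn{\tau = t_{act}(0.5 + 1.5 a)} while excitation exceeds activation
#' (activation builds up), and \eqn{\tau = t_{deact}/(0.5 + 1.5 a)}
#' otherwise (activation decays).
#'
#' @param a Current activation in \[0, 1\].
#' @param u_delayed Excitation (control delayed by the transmission delay).
#' @param t_act,t_deact Activation/deactivation time constants, s.
#' @return Time constant, s.
#' @export
activation_time_constant <- function(a, u_delayed, t_act = 0.010,
                                     t_deact = 0.040) {
  if (any(a < 0) || any(a > 1)) stop("activation must lie in [0, 1]")
  ifelse(u_delayed > a, t_act * (0.5 + 1.5 * a), t_deact / (0.5 + 1.5 * a))
}

#' One integration step of the activation dynamics
#'
#' Integrates \eqn{\dot a = (u - a)/\tau(a, u)} over `dt` with the classical
#' fourth-order Runge-Kutta scheme (the same scheme as the plant integrator),
#' holding the excitation constant over the step, then clamps to \[0, 1\].
#'
#' @param a Activation at the start of the step.
#' @param u_delayed Excitation held over the step.
#' @param dt Step, s (> 0).
#' @inheritParams activation_time_constant
#' @return Activation after the step.
#' @export
activation_step <- function(a, u_delayed, dt, t_act = 0.010, t_deact = 0.040) {
  stopifnot(dt > 0)
  f <- function(a) {
    ac <- pmin(pmax(a, 0), 1)
    (u_delayed - a) / activation_time_constant(ac, u_delayed, t_act, t_deact)
  }
  k1 <- f(a)
  k2 <- f(a + dt / 2 * k1)
  k3 <- f(a + dt / 2 * k2)
  k4 <- f(a + dt * k3)
  pmin(pmax(a + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0), 1)
}

#' Sample-grid delay buffer
#'
#' Ring-free delay line storing per-muscle signals on the integrator grid.
#' Reads at a lag return the sample recorded `lag_steps` steps earlier;
#' reads reaching before the start of the run return the value at step 0
#' (system assumed at rest at its target beforehand).
#'
#' @param n_signals Number of signals per sample.
#' @param n_steps Capacity (number of steps to retain).
#' @return An object of class `delay_buffer` (an environment).
#' @export
delay_buffer <- function(n_signals, n_steps) {
  e <- new.env(parent = emptyenv())
  e$data <- matrix(NA_real_, nrow = n_steps + 1L, ncol = n_signals)
  e$last <- -1L
  class(e) <- "delay_buffer"
  e
}

#' @rdname delay_buffer
#' @param buf A `delay_buffer`.
#' @param step Integer step index (0-based) being written.
#' @param x Signal vector to record.
#' @export
buffer_write <- function(buf, step, x) {
  buf$data[step + 1L, ] <- x
  buf$last <- max(buf$last, as.integer(step))
  invisible(buf)
}

#' @rdname delay_buffer
#' @param lag_steps Lag in steps (>= 0).
#' @export
buffer_read <- function(buf, step, lag_steps) {
  i <- max(as.integer(step) - as.integer(lag_steps), 0L)
  if (i > buf$last) stop("delay buffer read ahead of last write")
  buf$data[i + 1L, ]
}

#' One controller update
#'
#' Reads musculotendon length and velocity at lag `tau_fb` from the supplied
#' buffers, computes the PD feedback, composes the total control, and writes
#' it to the transmission buffer (from which the activation dynamics read at
#' lag `tau_trans`).
#'
#' @param step Integer step index (0-based) of the current time.
#' @param L_buf,Ldot_buf,u_buf Delay buffers for length, velocity, and
#'   control (length/velocity must be written up to `step`).
#' @param params A [controller_params()] object with `L0_MT` set.
#' @param muscles A [muscle_set()].
#' @param dt Step, s.
#' @return A list with per-muscle `u`, `u_raw`, `u_fb`, `u_ff` and
#'   `uff_norm_sq`.
#' @export
control_update <- function(step, L_buf, Ldot_buf, u_buf, params, muscles,
                           dt) {
  lag_fb <- as.integer(round(params$tau_fb / dt))
  L_d <- buffer_read(L_buf, step, lag_fb)
  Ld_d <- buffer_read(Ldot_buf, step, lag_fb)
  gains <- expand_gains(params)
  Vmax <- unname(vapply(muscles, function(m) m$V_max, 1))
  u_fb <- unname(gains$kp * (L_d - params$L0_MT) / params$L0_MT +
                   gains$kd * (Ld_d - params$Ldot0_MT) / Vmax)
  tc <- total_control(params$u_ff, u_fb, params$u_clip)
  buffer_write(u_buf, step, tc$u)
  list(u = tc$u, u_raw = tc$u_raw, u_fb = u_fb, u_ff = params$u_ff,
       uff_norm_sq = sum(params$u_ff^2))
}
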