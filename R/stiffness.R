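#' Fit the passive torque-angle model
#'
#' Least-squares fit of
#' \deqn{T_{passive} = K \theta + B \dot\theta + I \ddot\theta + C}
#' to a passive-torque / ankle-angle window.  Angle derivatives are formed
#' by second-order central differences and the endpoints are dropped from
#' the fit.  `K` is reported in N m/deg (with `B`, `I` in N m s/deg and
#' N m s^2/deg); the relative stiffness converts `K` to per-radian and
#' divides by half the critical stiffness, \eqn{2K_{rad}/(mgh)}.
#'
#' @param torque Passive torque series, N m.
#' @param theta_deg Ankle angle series, deg (same length).
#' @param dt Sample step, s.
#' @param m Mass above the ankle, kg.
#' @param g Gravitational acceleration, m/s^2.
#' @param h CoM height above the ankle, m.
#' @return An object of class `stiffness_fit` with components `K`, `B`,
#'   `I`, `C`, `relative_stiffness`, `residual_rms`, `se` (standard errors),
#'   `m`, `g`, `h`, `n` and the underlying `lm` fit.
#' @examples
#' syn <- synth_torque_angle(K = 2, B = 0.1, I = 1e-3, C = -5,
#'                           duration = 0.07, dt = 0.001, seed = 1)
#' fit <- fit_stiffness(syn$torque, syn$theta_deg, dt = 0.001,
#'                      m = 72, h = 0.914)
#' coef(fit)
#' @export
fit_stiffness <- function(torque, theta_deg, dt, m, g = 9.80665, h) {
  n <- length(torque)
  stopifnot(length(theta_deg) == n, dt > 0, m > 0, h > 0)
  if (n < 10) stop("need at least 10 samples to fit the torque-angle model")
  i <- 2:(n - 1)
  th <- theta_deg[i]
  thd <- (theta_deg[i + 1] - theta_deg[i - 1]) / (2 * dt)
  thdd <- (theta_deg[i + 1] - 2 * theta_deg[i] + theta_deg[i - 1]) / dt^2
  Tq <- torque[i]
  X <- cbind(theta = th, theta_dot = thd, theta_ddot = thdd)
  if (qr(cbind(X, 1))$rank < 4)
    stop("singular fit: degenerate angle series")
  fit <- stats::lm(Tq ~ th + thd + thdd)
  cf <- stats::coef(fit)
  # noiseless self-consistency fits are essentially perfect; the summary
  # warning carries no information here
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  K <- unname(cf["th"]); B <- unname(cf["thd"]); I <- unname(cf["thdd"])
  C <- unname(cf["(Intercept)"])
  structure(list(K = K, B = B, I = I, C = C,
                 relative_stiffness = relative_stiffness(K, m, g, h),
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 se = c(K = unname(se["th"]), B = unname(se["thd"]),
                        I = unname(se["thdd"]),
                        C = unname(se["(Intercept)"])),
                 m = m, g = g, h = h, n = length(i), lm = fit),
            class = "stiffness_fit")
}

#' @export
print.stiffness_fit <- function(x, ...) {
  cat("Passive torque-angle fit (T = K*theta + B*theta' + I*theta'' + C)\n")
  cat(sprintf("  K = %.4g N m/deg   B = %.4g N m s/deg\n", x$K, x$B))
  cat(sprintf("  I = %.4g N m s^2/deg   C = %.4g N m\n", x$I, x$C))
  cat(sprintf("  relative stiffness 2K/(mgh) = %.3f  (m = %g kg, h = %g m)\n",
              x$relative_stiffness, x$m, x$h))
  cat(sprintf("  residual RMS %.4g N m on %d samples\n", x$residual_rms, x$n))
  invisible(x)
}

#' @export
coef.stiffness_fit <- function(object, ...) {
  c(K = object$K, B = object$B, I = object$I, C = object$C)
}

#' @export
summary.stiffness_fit <- function(object, ...) {
  out <- data.frame(estimate = c(object$K, object$B, object$I, object$C),
                    se = unname(object$se),
                    row.names = c("K", "B", "I", "C"))
  out
}

#' @export
predict.stiffness_fit <- function(object, theta_deg, theta_dot = 0,
                                  theta_ddot = 0, ...) {
  object$K * theta_deg + object$B * theta_dot + object$I * theta_ddot +
    object$C
}

#' @export
residuals.stiffness_fit <- function(object, ...) {
  stats::residuals(object$lm)
}
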