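#' Synthetic torque-angle series with known ground truth
#'
#' Generates a smooth seeded random angle trajectory (sum of low-frequency
#' sinusoids) and the corresponding torque from the torque-angle model
#' `T = K*theta + B*theta' + I*theta'' + C` plus optional Gaussian noise.
#' Used as a recovery oracle for [fit_stiffness()].
#'
#' @param K,B,I,C True model parameters (per-degree units).
#' @param duration Series length, s.
#' @param dt Sample step, s.
#' @param noise_sd Torque noise standard deviation, N m.
#' @param seed Integer seed.
#' @param amplitude_deg Angle excursion scale, deg.
#' @return List with `time` (s), `theta_deg`, `theta_dot`, `theta_ddot`
#'   (analytic derivatives) and `torque`.
#' @export
synth_torque_angle <- function(K, B, I, C, duration = 0.07, dt = 0.001,
                               noise_sd = 0, seed = NULL,
                               amplitude_deg = 2) {
  n <- round(duration / dt) + 1
  if (n < 10) stop("duration/dt must give at least 10 samples")
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
  }
  t <- seq(0, by = dt, length.out = n)
  freqs <- stats::runif(3, 2, 12)          # Hz
  phases <- stats::runif(3, 0, 2 * pi)
  amps <- amplitude_deg * c(1, 0.5, 0.25)
  w <- 2 * pi * freqs
  th <- thd <- thdd <- numeric(n)
  for (k in 1:3) {
    th <- th + amps[k] * sin(w[k] * t + phases[k])
    thd <- thd + amps[k] * w[k] * cos(w[k] * t + phases[k])
    thdd <- thdd - amps[k] * w[k]^2 * sin(w[k] * t + phases[k])
  }
  # torque built from the same central-difference derivatives the
  # regression uses, so noiseless recovery is an exact self-consistency
  # check rather than limited by O(dt^2) discretization error
  i <- 2:(n - 1)
  thd_c <- thd; thdd_c <- thdd
  thd_c[i] <- (th[i + 1] - th[i - 1]) / (2 * dt)
  thdd_c[i] <- (th[i + 1] - 2 * th[i] + th[i - 1]) / dt^2
  torque <- K * th + B * thd_c + I * thdd_c + C
  if (noise_sd > 0) torque <- torque + stats::rnorm(n, 0, noise_sd)
  list(time = t, theta_deg = th, theta_dot = thd, theta_ddot = thdd,
       torque = torque)
}

#' Synthetic directional activation traces with known tuning
#'
#' Builds per-direction activation traces consisting of a constant baseline
#' plus a half-sine bump inside the observation window whose area follows a
#' cosine tuning curve around a preferred direction.  The constructed bump
#' areas are returned, so the integrated-response and similarity pipelines
#' have analytic ground truth.
#'
#' @param directions Direction angles, deg.
#' @param preferred_deg Preferred direction of the tuning curve, deg.
#' @param peak_area Bump area in the peak direction, s.
#' @param baseline Constant baseline activation.
#' @param onset Perturbation onset, ms.
#' @param dt Sample step, s.
#' @param T_total Trace length, ms.
#' @param rectified Floor the tuning at zero (half-wave rectified cosine,
#'   like a muscle that is silent for off-directions).
#' @param seed Optional seed for small baseline jitter (none when `NULL`).
#' @param noise_sd Baseline jitter standard deviation.
#' @return List with `time_ms`, `traces` (time x directions matrix),
#'   `areas` (true bump areas, s) and `tuning` (unrectified cosine values).
#' @export
synth_activation_traces <- function(directions = standard_directions(),
                                    preferred_deg = 90, peak_area = 0.01,
                                    baseline = 0.1, onset = 500, dt = 0.001,
                                    T_total = 1000, rectified = TRUE,
                                    seed = NULL, noise_sd = 0) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
  }
  t_ms <- seq(0, T_total, by = dt * 1000)
  tuning <- cos((directions - preferred_deg) * pi / 180)
  areas <- peak_area * if (rectified) pmax(tuning, 0) else tuning
  lo <- onset + 70; hi <- onset + 270
  traces <- matrix(baseline, length(t_ms), length(directions))
  inwin <- t_ms >= lo & t_ms <= hi
  # half-sine bump normalized so its trapezoidal integral on this grid is
  # exactly one (the constructed areas are then exact discrete truth)
  s <- (t_ms[inwin] - lo) / (hi - lo)
  bump <- sin(pi * s)
  bump <- bump / trapz_integral(t_ms[inwin] / 1000, bump)
  for (k in seq_along(directions))
    traces[inwin, k] <- traces[inwin, k] + areas[k] * bump
  if (noise_sd > 0)
    traces <- traces + matrix(stats::rnorm(length(traces), 0, noise_sd),
                              nrow(traces))
  list(time_ms = t_ms, traces = traces, areas = areas, tuning = tuning,
       directions = directions, onset = onset)
}
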