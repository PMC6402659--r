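#' Baseline activation before perturbation onset
#'
#' Mean activation over the window 150 to 50 ms before the onset.
#'
#' @param trace Activation series of one muscle.
#' @param time_ms Sample times, ms (same length as `trace`).
#' @param onset Perturbation onset, ms.
#' @return Baseline activation (dimensionless).
#' @export
baseline_activation <- function(trace, time_ms, onset) {
  lo <- onset - 150; hi <- onset - 50
  if (min(time_ms) > lo)
    stop("trace does not cover the pre-onset baseline window")
  sel <- time_ms >= lo - 1e-9 & time_ms <= hi + 1e-9
  mean(trace[sel])
}

#' Integrated muscle response
#'
#' Trapezoidal integral of the baseline-subtracted activation over the
#' observation window 70-270 ms after perturbation onset; units are seconds
#' (time integrated in s).  May be negative when activation drops below
#' baseline.
#'
#' @inheritParams baseline_activation
#' @param a_baseline Baseline activation (see [baseline_activation()]).
#' @return Integrated response, s.
#' @export
integrated_response <- function(trace, time_ms, onset, a_baseline) {
  lo <- onset + 70; hi <- onset + 270
  if (max(time_ms) < hi || min(time_ms) > lo)
    stop("trace does not cover the observation window")
  sel <- time_ms >= lo - 1e-9 & time_ms <= hi + 1e-9
  trapz_integral(time_ms[sel] / 1000, trace[sel] - a_baseline)
}

#' Normalize a 12-direction profile to \[0, 1\]
#'
#' Divides by the maximum over the directions so the largest response maps
#' to one; negative scaled entries are clipped to zero (the number clipped
#' is recorded in the `"n_clipped"` attribute).
#'
#' @param values Per-direction integrated responses.
#' @return Vector in \[0, 1\] with `max == 1`.
#' @export
normalize_unit_max <- function(values) {
  if (all(values <= 0)) stop("degenerate profile: no positive response")
  out <- values / max(values)
  ncl <- sum(out < 0)
  out <- pmax(out, 0)
  attr(out, "n_clipped") <- ncl
  out
}

#' Normalize a 12-direction profile to \[-1, 1\]
#'
#' Affine min-max map `2 * (v - min) / (max - min) - 1`, the general
#' normalization applied before cosine-similarity comparison.
#'
#' @param values Per-direction integrated responses.
#' @return Vector in \[-1, 1\] with the minimum at -1 and maximum at +1.
#' @export
normalize_signed <- function(values) {
  rng <- range(values)
  if (rng[1] == rng[2]) stop("degenerate profile: constant vector")
  2 * (values - rng[1]) / (rng[2] - rng[1]) - 1
}

#' Cosine similarity
#'
#' @param v1,v2 Nonzero vectors of equal length.
#' @return `sum(v1 * v2) / (|v1| |v2|)`, in \[-1, 1\]; +1 for identical
#'   (or positively proportional) vectors.
#' @export
cosine_similarity <- function(v1, v2) {
  stopifnot(length(v1) == length(v2))
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("cosine similarity undefined for zero vector")
  sum(v1 * v2) / (n1 * n2)
}

#' Monte-Carlo null distribution of cosine similarity
#'
#' Draws `n` random 12-vectors with components uniform on \[-1, 1\], computes
#' their cosine similarities with the reference vector, and summarizes the
#' null with a normal approximation.
#'
#' @param v_ref Reference vector (nonzero).
#' @param n Number of random vectors (>= 1000; 100,000 for the standard
#'   null).
#' @param seed Integer seed.
#' @param observed Optional observed similarity; when supplied, the value
#'   of the normal CDF at `observed` is returned as `cumulative_prob`.
#' @return List with `mean`, `sd`, `n` and (when `observed` is given)
#'   `cumulative_prob`.
#' @export
random_similarity_null <- function(v_ref, n = 100000, seed = NULL,
                                   observed = NULL) {
  stopifnot(n >= 1000)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(seed)
  }
  d <- length(v_ref)
  nref <- sqrt(sum(v_ref^2))
  if (nref == 0) stop("zero reference vector")
  # block the draws to bound memory at large n
  block <- 10000L
  sims <- numeric(n)
  done <- 0L
  while (done < n) {
    nb <- min(block, n - done)
    R <- matrix(stats::runif(nb * d, -1, 1), nb, d)
    sims[done + seq_len(nb)] <-
      as.numeric(R %*% v_ref) / (sqrt(rowSums(R^2)) * nref)
    done <- done + nb
  }
  out <- list(mean = mean(sims), sd = stats::sd(sims), n = n)
  if (!is.null(observed))
    out$cumulative_prob <- stats::pnorm(observed, out$mean, out$sd)
  out
}

#' Directional muscle-response profile
#'
#' Runs (or accepts) one trajectory per perturbation direction and collects
#' each muscle's integrated response, plus the unit-max and signed
#' normalizations used for radar plots and cosine-similarity comparison.
#'
#' @param trajectories Named or ordered list of `stance_trajectory` objects,
#'   one per direction in `directions`.
#' @param directions Direction angles, degrees (default the 12 standard
#'   directions).
#' @param onset Perturbation onset, ms (taken from the first trajectory's
#'   spec when `NULL`).
#' @return An object of class `response_profile`: list with `directions`,
#'   `integrated` (directions x muscles matrix, s), `normalized_01`,
#'   `normalized_signed`, `muscles`.
#' @export
response_profile <- function(trajectories,
                             directions = standard_directions(),
                             onset = NULL) {
  stopifnot(length(trajectories) == length(directions))
  tr1 <- trajectories[[1]]
  if (is.null(onset)) {
    if (is.null(tr1$perturbation)) stop("onset not supplied")
    onset <- tr1$perturbation$onset
  }
  muscles <- tr1$muscles
  integ <- matrix(NA_real_, length(directions), length(muscles),
                  dimnames = list(paste0("dir_", directions), muscles))
  for (k in seq_along(trajectories)) {
    tr <- trajectories[[k]]
    t_ms <- tr$time * 1000
    for (i in seq_along(muscles)) {
      ab <- baseline_activation(tr$activations[, i], t_ms, onset)
      integ[k, i] <- integrated_response(tr$activations[, i], t_ms, onset, ab)
    }
  }
  n01 <- apply(integ, 2, function(v)
    tryCatch(as.numeric(normalize_unit_max(v)),
             error = function(e) rep(NA_real_, length(v))))
  nsg <- apply(integ, 2, function(v)
    tryCatch(normalize_signed(v),
             error = function(e) rep(NA_real_, length(v))))
  dimnames(n01) <- dimnames(nsg) <- dimnames(integ)
  structure(list(directions = directions, integrated = integ,
                 normalized_01 = n01, normalized_signed = nsg,
                 muscles = muscles),
            class = "response_profile")
}

#' @export
print.response_profile <- function(x, ...) {
  cat(sprintf("Directional response profile: %d directions x %d muscles\n",
              length(x$directions), length(x$muscles)))
  print(round(x$integrated, 6))
  invisible(x)
}

#' Radar plot of a response profile
#'
#' Twelve-spoke polar plot of the unit-max-normalized responses, one panel
#' per muscle.
#'
#' @param x A `response_profile`.
#' @param muscles Subset of muscle names (default all).
#' @param ... Unused.
#' @export
plot.response_profile <- function(x, muscles = x$muscles, ...) {
  k <- length(muscles)
  nc <- ceiling(sqrt(k))
  op <- graphics::par(mfrow = c(ceiling(k / nc), nc), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  th <- x$directions * pi / 180
  for (m in muscles) {
    v <- x$normalized_01[, m]
    v[is.na(v)] <- 0
    xx <- c(v * cos(th), v[1] * cos(th[1]))
    yy <- c(v * sin(th), v[1] * sin(th[1]))
    graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                   axes = FALSE, xlab = "", ylab = "", main = m)
    for (r in c(0.5, 1))
      graphics::lines(r * cos(seq(0, 2 * pi, length.out = 73)),
                      r * sin(seq(0, 2 * pi, length.out = 73)),
                      col = "grey80")
    graphics::segments(0, 0, cos(th), sin(th), col = "grey90")
    graphics::polygon(xx, yy, col = grDevices::adjustcolor("red", 0.4),
                      border = "red")
  }
  invisible(x)
}

#' Passive ankle torque series
#'
#' Ankle torque attributable to passive muscle elasticity plus the active
#' force of the constant feed-forward activation (not the instantaneous
#' activation), evaluated over the pre-reactive window after perturbation
#' onset:
#' \deqn{T_{passive} = -\sum_i f^M_{o,i}\left(a_{ff,i} f_L f_V + f_{PE}\right)
#'   ma_{i,ankle}.}
#' The sign convention reports plantarflexion torque as positive, paired
#' with the dorsiflexion-positive ankle angle.
#'
#' @param traj A `stance_trajectory`.
#' @param muscles The [muscle_set()] used in the run.
#' @param u_ff Feed-forward activation vector (a `uff_candidate` or plain
#'   numeric).
#' @param window Window after onset, ms (default `c(0, 70)`).
#' @param ankle_joint Index or name of the ankle joint (default 1).
#' @param curves A [hill_curves()] object.
#' @return A data frame with `time_ms` (since onset), `theta_ankle_deg`
#'   (dorsiflexion-positive, relative to the run's initial angle) and
#'   `torque` (N m, plantarflexion-positive).
#' @export
passive_torque <- function(traj, muscles, u_ff, window = c(0, 70),
                           ankle_joint = 1, curves = hill_curves()) {
  if (inherits(u_ff, "uff_candidate")) u_ff <- u_ff$u_ff
  mm <- muscle_matrices(muscles)
  if (is.character(ankle_joint))
    ankle_joint <- match(ankle_joint, traj$joints)
  onset <- if (!is.null(traj$perturbation)) traj$perturbation$onset else 0
  t_ms <- traj$time * 1000
  sel <- which(t_ms >= onset + window[1] - 1e-9 &
                 t_ms <= onset + window[2] + 1e-9)
  if (!length(sel)) stop("trajectory does not cover the passive window")
  l <- sweep(sweep(traj$L_MT[sel, , drop = FALSE], 2, mm$L_slack), 2,
             mm$L_opt, "/")
  v <- sweep(traj$Ldot_MT[sel, , drop = FALSE], 2, mm$V_max, "/")
  Fm <- matrix(NA_real_, length(sel), length(muscles))
  for (i in seq_along(muscles))
    Fm[, i] <- mm$F0[i] *
      (u_ff[i] * active_force_length(l[, i], curves) *
         force_velocity(v[, i], curves) +
         passive_force_length(l[, i], curves))
  torque <- -as.numeric(Fm %*% mm$ma[, ankle_joint])
  data.frame(
    time_ms = t_ms[sel] - onset,
    theta_ankle_deg = (traj$theta[sel, ankle_joint] -
                         traj$theta[1, ankle_joint]) * 180 / pi,
    torque = torque)
}

#' Relative ankle stiffness
#'
#' \eqn{2 K / (m g h)} with the stiffness converted from N m/deg to
#' N m/rad; \eqn{m g h} is the critical stiffness of the equivalent
#' inverted pendulum (mass above the ankle times gravity times CoM height
#' above the ankle).
#'
#' @param K Ankle stiffness, N m/deg.
#' @param m Mass above the ankle, kg.
#' @param g Gravitational acceleration, m/s^2.
#' @param h CoM height above the ankle, m.
#' @return Dimensionless relative stiffness.
#' @export
relative_stiffness <- function(K, m, g = 9.80665, h) {
  stopifnot(m > 0, h > 0)
  2 * (K * 180 / pi) / (m * g * h)
}
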