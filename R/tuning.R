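#' Per-group PD gain-ratio table
#'
#' Base (P-multiplier, D-multiplier) ratios per muscle group used in the
#' feed-forward generation stage: the group gains are
#' `k_p = p_ratio * P`, `k_d = d_ratio * D` for sweep scalars P and D.
#' The default table covers the eleven standard groups; `frontal_analogs`
#' appends hip ab/adductor rows (copies of the hip flexor/extensor ratios)
#' for frontal-plane plants.
#'
#' @param frontal_analogs Append `hip_abductor`/`hip_adductor` rows.
#' @return A data frame with columns `group`, `p_ratio`, `d_ratio`.
#' @export
gain_ratio_table <- function(frontal_analogs = FALSE) {
  tab <- data.frame(
    group = c("lumbar_extensor", "lumbar_flexor", "hip_extensor",
              "hip_flexor", "knee_extensor", "knee_flexor",
              "ankle_extensor", "ankle_flexor", "subtalar_evertor",
              "subtalar_invertor", "biarticular"),
    p_ratio = c(0.50, 0.48, 0.45, 0.50, 0.33, 0.28, 0.17, 0.30, 0.50,
                0.49, 0.39),
    d_ratio = c(0.23, 0.11, 0.05, 0.16, 0.05, 0.23, 0.06, 0.27, 0.11,
                0.05, 0.05),
    stringsAsFactors = FALSE)
  if (frontal_analogs)
    tab <- rbind(tab, data.frame(
      group = c("hip_abductor", "hip_adductor"),
      p_ratio = c(0.50, 0.45), d_ratio = c(0.16, 0.05)))
  tab
}

#' Per-group gains from the ratio table
#'
#' @param table A gain-ratio table (see [gain_ratio_table()]).
#' @param P,D Sweep scalars (> 0).
#' @return A list with named vectors `k_p` and `k_d`.
#' @export
base_gains <- function(table, P, D) {
  stopifnot(P > 0, D > 0, all(table$p_ratio > 0), all(table$d_ratio > 0))
  k_p <- stats::setNames(table$p_ratio * P, table$group)
  k_d <- stats::setNames(table$d_ratio * D, table$group)
  list(k_p = k_p, k_d = k_d)
}

#' Feed-forward candidate from an activation trace
#'
#' Each feed-forward component is the trapezoidal time-average of the
#' muscle's activation over the late window of a standing run (by default
#' 3000-5000 ms).
#'
#' @param traj A `stance_trajectory` from a run that stood the full horizon.
#' @param window Averaging window `c(t_lo, t_hi)`, ms.
#' @param provenance Optional list (e.g. the generating `P`, `D`) carried on
#'   the candidate.
#' @return An object of class `uff_candidate`: list with `u_ff`, `norm_sq`,
#'   `provenance`, `stood`.
#' @export
uff_from_trace <- function(traj, window = c(3000, 5000), provenance = NULL) {
  t_ms <- traj$time * 1000
  if (min(t_ms) > window[1] || max(t_ms) < window[2])
    stop("trace does not cover the averaging window")
  if (!isTRUE(traj$stood))
    stop("feed-forward candidates require a run that stood the full horizon")
  sel <- t_ms >= window[1] & t_ms <= window[2]
  tt <- t_ms[sel]
  u_ff <- apply(traj$activations[sel, , drop = FALSE], 2, function(a)
    trapz_integral(tt, a) / (tt[length(tt)] - tt[1]))
  structure(list(u_ff = unname(u_ff), muscle = traj$muscles,
                 norm_sq = sum(u_ff^2), provenance = provenance,
                 stood = TRUE),
            class = "uff_candidate")
}

#' @export
print.uff_candidate <- function(x, ...) {
  cat(sprintf("u_ff candidate: ||u_ff||^2 = %.4g", x$norm_sq))
  if (!is.null(x$provenance))
    cat(sprintf("  (P = %g, D = %g)", x$provenance$P, x$provenance$D))
  cat("\n")
  invisible(x)
}

# Internal trapezoidal quadrature on an arbitrary grid
trapz_integral <- function(t, y) {
  n <- length(t)
  sum((y[-1] + y[-n]) / 2 * diff(t))
}

#' Sweep (P, D) to generate feed-forward candidates
#'
#' First stage of the parameter adjustment: for each (P, D) pair, an
#' unperturbed run with zero feed-forward and zero delays is simulated with
#' the ratio-table gains.  Runs that stand the full horizon yield a
#' candidate by [uff_from_trace()]; failed runs are recorded but yield
#' nothing.  Candidates with duplicated squared norm (within 1e-9) are
#' dropped.
#'
#' @param config,muscles Plant and muscle set.
#' @param table Gain-ratio table covering every muscle group.
#' @param P_values,D_values Sweep grids (paper-scale default 1.0-3.0 by 0.1).
#' @param T_simu Horizon, ms.
#' @param dt Step, s.
#' @param window Averaging window, ms.
#' @param u_clip Control bounds for the generation runs.
#' @param verbose Print one line per grid point.
#' @return List of `uff_candidate` objects, sorted by increasing norm,
#'   with an attribute `"grid"`: a data frame of all (P, D) and outcomes.
#' @export
sweep_uff_candidates <- function(config, muscles, table = gain_ratio_table(),
                                 P_values = seq(1, 3, by = 0.1),
                                 D_values = seq(1, 3, by = 0.1),
                                 T_simu = 5000, dt = 0.001,
                                 window = c(3000, 5000),
                                 u_clip = c(0.001, 1), verbose = FALSE) {
  stopifnot(length(P_values) > 0, length(D_values) > 0)
  mm <- muscle_matrices(muscles)
  groups <- unique(mm$group)
  miss <- setdiff(groups, table$group)
  if (length(miss))
    stop("gain table lacks groups: ", paste(miss, collapse = ", "))
  cands <- list()
  grid <- expand.grid(P = P_values, D = D_values)
  grid$stood <- FALSE
  grid$norm_sq <- NA_real_
  for (r in seq_len(nrow(grid))) {
    bg <- base_gains(table, grid$P[r], grid$D[r])
    ctrl <- controller_params(
      u_ff = rep(0, length(muscles)),
      k_p = bg$k_p[groups], k_d = bg$k_d[groups], group_map = mm$group,
      tau_fb = 0, tau_trans = 0, u_clip = u_clip)
    traj <- simulate_stance(config, muscles, ctrl, perturbation = NULL,
                            T_simu = T_simu, dt = dt)
    if (traj$stood) {
      cand <- uff_from_trace(traj, window,
                             provenance = list(P = grid$P[r], D = grid$D[r]))
      grid$stood[r] <- TRUE
      grid$norm_sq[r] <- cand$norm_sq
      dup <- any(vapply(cands, function(cd)
        abs(cd$norm_sq - cand$norm_sq) < 1e-9, TRUE))
      if (!dup) cands[[length(cands) + 1L]] <- cand
    }
    if (verbose)
      message(sprintf("P = %.2f D = %.2f: %s", grid$P[r], grid$D[r],
                      if (grid$stood[r])
                        sprintf("stood, ||u_ff||^2 = %.4g", grid$norm_sq[r])
                      else "fell"))
  }
  ord <- order(vapply(cands, function(cd) cd$norm_sq, 1))
  structure(cands[ord], grid = grid)
}

#' Select candidates at equal norm intervals
#'
#' Picks the candidates whose squared norms are nearest to `n` equally
#' spaced targets spanning the observed range of squared norms; ties are
#' broken toward the smaller norm, duplicates collapsed.
#'
#' @param candidates List of `uff_candidate` objects.
#' @param n Number of selections (>= 2).
#' @return Subset of `candidates`, ordered by increasing `norm_sq`.
#' @export
select_by_norm <- function(candidates, n) {
  stopifnot(n >= 2, length(candidates) > 0)
  norms <- vapply(candidates, function(cd) cd$norm_sq, 1)
  if (length(candidates) <= n) {
    if (length(candidates) < n)
      warning("fewer candidates than requested; returning all")
    return(candidates[order(norms)])
  }
  targets <- seq(min(norms), max(norms), length.out = n)
  picks <- integer(0)
  for (tg in targets) {
    d <- abs(norms - tg)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(norms[best])]
    picks <- c(picks, best)
  }
  picks <- unique(picks)
  candidates[picks[order(norms[picks])]]
}

#' Objective configuration
#'
#' @param w_fail,w_pos Weights of the fall and posture terms (defaults
#'   10000 and 1).
#' @param T_simu Horizon, ms (default 5000).
#' @return An `objective_config` list.
#' @export
objective_config <- function(w_fail = 10000, w_pos = 1, T_simu = 5000) {
  stopifnot(w_fail >= 0, w_pos >= 0, T_simu > 0)
  structure(list(w_fail = w_fail, w_pos = w_pos, T_simu = T_simu),
            class = "objective_config")
}

#' Standing objective
#'
#' \eqn{J = w_{fail} J_{fail} + w_{pos} J_{pos}} with
#' \eqn{J_{fail} = (T_{simu} - T_{fall})/T_{fall}} (a run that stands the
#' whole horizon scores exactly 0; an immediate fall is assigned the finite
#' sentinel 1e9) and \eqn{J_{pos} = \sum_j \int_0^{T_{fall}}
#' |\theta_j(t) - \theta_j(0)|\,dt} (rad s, absolute deviations).
#'
#' @param traj A `stance_trajectory`.
#' @param config An [objective_config()].
#' @param initial_pose Reference pose (defaults to the trajectory's first
#'   sample).
#' @return A list with `J`, `J_fail`, `J_pos`, `T_fall`.
#' @export
objective_J <- function(traj, config = objective_config(),
                        initial_pose = NULL) {
  T_fall <- traj$t_fall
  J_fail <- if (T_fall <= 0) 1e9 else (config$T_simu - T_fall) / T_fall
  if (is.null(initial_pose)) initial_pose <- traj$theta[1, ]
  dev <- abs(sweep(traj$theta, 2, initial_pose))
  J_pos <- sum(apply(dev, 2, function(d) trapz_integral(traj$time, d)))
  list(J = config$w_fail * J_fail + config$w_pos * J_pos,
       J_fail = J_fail, J_pos = J_pos, T_fall = T_fall)
}

#' CMA-ES configuration
#'
#' @param lambda Population size (>= 4; default 18).
#' @param sigma Initial step size (default 0.005).
#' @param max_iter Iteration budget (default 1500; scale down for
#'   desk-scale studies).
#' @param seed Integer seed for the search (optional).
#' @param lower,upper Box bounds handled by penalty-free reflection
#'   (gains are bounded below by 0).
#' @param ftarget Stop as soon as the best objective falls to or below this
#'   value (optional).
#' @param tol_stagnation Stop after this many consecutive iterations
#'   without improvement of the best objective (optional).
#' @param stop_fn Optional zero-argument function polled after each
#'   iteration; the search halts when it returns `TRUE` (used e.g. to stop
#'   once a standing solution has been evaluated).
#' @return A `cma_config` list.
#' @export
cma_config <- function(lambda = 18, sigma = 0.005, max_iter = 1500,
                       seed = NULL, lower = 0, upper = Inf,
                       ftarget = NULL, tol_stagnation = NULL,
                       stop_fn = NULL) {
  stopifnot(lambda >= 4, sigma > 0, max_iter >= 1)
  structure(list(lambda = lambda, sigma = sigma, max_iter = max_iter,
                 seed = seed, lower = lower, upper = upper,
                 ftarget = ftarget, tol_stagnation = tol_stagnation,
                 stop_fn = stop_fn),
            class = "cma_config")
}

#' Covariance matrix adaptation evolution strategy
#'
#' Standard (mu/mu_w, lambda)-CMA-ES minimizer with rank-one and rank-mu
#' covariance updates and cumulative step-size adaptation.  Box constraints
#' are handled by mirrored reflection of infeasible coordinates (no
#' penalty).  Deterministic for a fixed seed.
#'
#' @param fn Objective function of a numeric vector.
#' @param x0 Initial mean.
#' @param config A [cma_config()].
#' @return A list with `par`, `value`, `history` (data frame with one row
#'   per iteration: `iter`, `best`, `sigma`), `evaluations`, `converged`
#'   (TRUE unless the budget was exhausted while `ftarget` was set and
#'   unmet).
#' @export
cma_es <- function(fn, x0, config = cma_config()) {
  n <- length(x0)
  lambda <- config$lambda
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  reflect <- function(x) {
    lo <- config$lower; hi <- config$upper
    for (r in 1:10) {
      below <- x < lo
      x[below] <- 2 * lo - x[below]
      above <- x > hi
      if (any(is.finite(hi) & above)) x[above] <- 2 * hi - x[above]
      if (all(x >= lo & x <= hi)) break
    }
    pmin(pmax(x, lo), if (all(is.finite(hi))) hi else x)
  }

  if (!is.null(config$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, globalenv()), add = TRUE)
    set.seed(config$seed)
  }

  xmean <- as.numeric(x0)
  sigma <- config$sigma
  pc <- ps <- numeric(n)
  B <- diag(n); D <- rep(1, n); C <- diag(n)
  invsqrtC <- diag(n)
  eigeneval <- 0; counteval <- 0
  best_x <- reflect(xmean); best_f <- fn(best_x); counteval <- 1
  hist <- vector("list", config$max_iter)
  stagnation <- 0L

  for (iter in seq_len(config$max_iter)) {
    Z <- matrix(stats::rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)
    X <- xmean + sigma * Y
    Xr <- apply(X, 2, reflect)
    if (n == 1) Xr <- matrix(Xr, 1)
    f <- apply(Xr, 2, fn)
    counteval <- counteval + lambda
    ord <- order(f)
    improved <- f[ord[1]] < best_f
    if (improved) { best_f <- f[ord[1]]; best_x <- Xr[, ord[1]] }
    stagnation <- if (improved) 0L else stagnation + 1L

    sel <- ord[seq_len(mu)]
    Ysel <- (Xr[, sel, drop = FALSE] - xmean) / sigma
    yw <- as.numeric(Ysel %*% w)
    xmean <- xmean + sigma * yw
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.numeric(invsqrtC %*% yw)
    hsig <- sum(ps^2) / (1 - (1 - cs)^(2 * counteval / lambda)) / n <
      2 + 4 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * yw
    C <- (1 - c1 - cmu) * C +
      c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Ysel %*% (w * t(Ysel))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    if (counteval - eigeneval > lambda / (c1 + cmu) / n / 10) {
      eigeneval <- counteval
      C <- (C + t(C)) / 2
      eig <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eig$values, 1e-20))
      B <- eig$vectors
      invsqrtC <- B %*% (t(B) / D)
    }

    hist[[iter]] <- data.frame(iter = iter, best = best_f, sigma = sigma)
    if (!is.null(config$ftarget) && best_f <= config$ftarget) break
    if (!is.null(config$tol_stagnation) &&
        stagnation >= config$tol_stagnation) break
    if (!is.null(config$stop_fn) && isTRUE(config$stop_fn())) break
  }
  history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  converged <- is.null(config$ftarget) || best_f <= config$ftarget
  list(par = best_x, value = best_f, history = history,
       evaluations = counteval, converged = converged)
}

#' Optimize grouped PD gains for one perturbation direction
#'
#' Second stage of the parameter adjustment: CMA-ES over the per-group
#' (k_p, k_d) vector, each candidate evaluated by a full perturbed
#' closed-loop simulation scored with [objective_J()].  Gains are bounded
#' below by zero via mirrored reflection.
#'
#' @param config,muscles Plant and muscle set.
#' @param uff A `uff_candidate` (or plain numeric feed-forward vector).
#' @param direction_deg Perturbation direction, degrees.
#' @param cma A [cma_config()].
#' @param objective An [objective_config()].
#' @param init_gains Optional list with named `k_p`, `k_d` starting means;
#'   defaults to the ratio table at P = D = 1, a deliberately low-gain
#'   start since delayed loops tolerate less gain than the zero-delay
#'   generation stage.
#' @param table Ratio table used for the default start.
#' @param perturbation Base [perturbation_spec()] whose direction is
#'   overridden.
#' @param tau_fb,tau_trans Controller delays, s.
#' @param dt Step, s.
#' @param stop_on_stand Halt the search as soon as a standing candidate
#'   (`J_fail = 0`) has been evaluated, and return the best standing
#'   solution seen.  Useful for feasibility studies where only the
#'   existence of a standing solution within the budget matters.
#' @return A list with `k_p`, `k_d` (named per-group), `J`, `J_fail`,
#'   `J_pos`, `history`, `converged` (TRUE when a standing solution was
#'   found), `evaluations`.
#' @export
optimize_gains <- function(config, muscles, uff, direction_deg,
                           cma = cma_config(), objective = objective_config(),
                           init_gains = NULL, table = gain_ratio_table(),
                           perturbation = perturbation_spec(),
                           tau_fb = 0.040, tau_trans = 0.040, dt = 0.001,
                           stop_on_stand = FALSE) {
  u_ff <- if (inherits(uff, "uff_candidate")) uff$u_ff else as.numeric(uff)
  mm <- muscle_matrices(muscles)
  groups <- unique(mm$group)
  ng <- length(groups)
  if (is.null(init_gains)) {
    bg <- base_gains(table, 1, 1)
    init_gains <- list(k_p = bg$k_p[groups], k_d = bg$k_d[groups])
  }
  x0 <- c(unname(init_gains$k_p[groups]), unname(init_gains$k_d[groups]))
  pert <- perturbation
  pert$direction_deg <- direction_deg %% 360

  tracker <- new.env(parent = emptyenv())
  tracker$best_standing <- NULL
  tracker$best_standing_J <- Inf
  eval_gains <- function(x) {
    ctrl <- controller_params(
      u_ff = u_ff,
      k_p = stats::setNames(x[seq_len(ng)], groups),
      k_d = stats::setNames(x[ng + seq_len(ng)], groups),
      group_map = mm$group, tau_fb = tau_fb, tau_trans = tau_trans)
    traj <- simulate_stance(config, muscles, ctrl, pert,
                            T_simu = objective$T_simu, dt = dt)
    jj <- objective_J(traj, objective)
    if (jj$J_fail == 0 && jj$J < tracker$best_standing_J) {
      tracker$best_standing <- x
      tracker$best_standing_J <- jj$J
    }
    jj$J
  }
  if (stop_on_stand)
    cma$stop_fn <- function() !is.null(tracker$best_standing)

  res <- cma_es(eval_gains, x0, cma)
  par <- if (stop_on_stand && !is.null(tracker$best_standing))
    tracker$best_standing else res$par
  k_p <- stats::setNames(par[seq_len(ng)], groups)
  k_d <- stats::setNames(par[ng + seq_len(ng)], groups)
  ctrl <- controller_params(u_ff = u_ff, k_p = k_p, k_d = k_d,
                            group_map = mm$group,
                            tau_fb = tau_fb, tau_trans = tau_trans)
  traj <- simulate_stance(config, muscles, ctrl, pert,
                          T_simu = objective$T_simu, dt = dt)
  jj <- objective_J(traj, objective)
  list(k_p = k_p, k_d = k_d, J = jj$J, J_fail = jj$J_fail, J_pos = jj$J_pos,
       history = res$history, evaluations = res$evaluations,
       converged = jj$J_fail == 0, direction_deg = pert$direction_deg,
       uff_norm_sq = sum(u_ff^2))
}
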