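test_that("gain ratio table covers the standard groups with the documented ratios", {
  tab <- gain_ratio_table()
  expect_equal(nrow(tab), 11)
  bg <- base_gains(tab, 1, 1)
  expect_equal(unname(bg$k_p["lumbar_extensor"]), 0.50)
  expect_equal(unname(bg$k_d["lumbar_extensor"]), 0.23)
  bg2 <- base_gains(tab, 2, 3)
  expect_equal(unname(bg2$k_p["ankle_extensor"]), 0.17 * 2)
  expect_equal(unname(bg2$k_d["ankle_extensor"]), 0.06 * 3)
  # linear scaling in P and D
  expect_equal(base_gains(tab, 2.5, 1)$k_p, 2.5 * base_gains(tab, 1, 1)$k_p)
  tf <- gain_ratio_table(frontal_analogs = TRUE)
  expect_true(all(c("hip_abductor", "hip_adductor") %in% tf$group))
})

test_that("feed-forward averaging matches quadrature oracles", {
  # constant activation -> the constant
  t <- seq(0, 5, by = 0.001)
  traj <- structure(list(time = t,
                         activations = cbind(m1 = rep(0.1, length(t)),
                                             m2 = 0.2 + 0.05 * sin(2 * pi * t)),
                         muscles = c("m1", "m2"), stood = TRUE),
                    class = "stance_trajectory")
  cd <- uff_from_trace(traj, window = c(3000, 5000))
  expect_equal(cd$u_ff[1], 0.1, tolerance = 1e-12)
  # zero-mean oscillation over whole periods averages out
  expect_equal(cd$u_ff[2], 0.2, tolerance = 1e-6)
  expect_equal(cd$norm_sq, sum(cd$u_ff^2))
  # fine-grid quadrature oracle on an irregular trace
  f <- function(tt) 0.1 + 0.03 * sin(3 * tt) + 0.01 * cos(7 * tt)
  traj2 <- structure(list(time = t, activations = cbind(m = f(t)),
                          muscles = "m", stood = TRUE),
                     class = "stance_trajectory")
  tt_fine <- seq(3, 5, by = 1e-5)
  oracle <- mean(diff(tt_fine) * (f(tt_fine)[-1] + f(tt_fine)[-length(tt_fine)]) / 2) *
    length(diff(tt_fine)) / 2
  expect_equal(uff_from_trace(traj2)$u_ff[1], oracle, tolerance = 1e-6)
  # a fallen run is rejected
  traj$stood <- FALSE
  expect_error(uff_from_trace(traj), "stood")
  expect_error(uff_from_trace(structure(list(time = t[1:100],
    activations = cbind(rep(1, 100)), muscles = "m", stood = TRUE),
    class = "stance_trajectory")), "window")
})

test_that("norm-interval selection matches the brute-force rule", {
  mk_cand <- function(n2) structure(list(u_ff = sqrt(n2), norm_sq = n2),
                                    class = "uff_candidate")
  cands <- lapply(c(1, 2, 3, 4, 5), mk_cand)
  sel <- select_by_norm(cands, 3)
  expect_equal(vapply(sel, function(cd) cd$norm_sq, 1), c(1, 3, 5))
  expect_length(select_by_norm(cands, 5), 5)
  expect_warning(sel2 <- select_by_norm(cands[1:2], 4), "fewer")
  expect_length(sel2, 2)
  # irregular norms: exhaustive nearest-to-target oracle
  set.seed(9)
  norms <- sort(runif(9, 0, 10))
  cands2 <- lapply(norms, mk_cand)
  n <- 4
  targets <- seq(min(norms), max(norms), length.out = n)
  oracle <- sort(unique(vapply(targets, function(tg) {
    d <- abs(norms - tg)
    cand <- which(d == min(d))
    if (length(cand) > 1) cand <- cand[which.min(norms[cand])]
    norms[cand]
  }, 1)))
  got <- vapply(select_by_norm(cands2, n), function(cd) cd$norm_sq, 1)
  expect_equal(got, oracle)
  # output norms nondecreasing
  expect_true(all(diff(got) >= 0))
})

test_that("the standing objective scores fall time and pose deviation", {
  t <- seq(0, 5, by = 0.001)
  th0 <- c(0.1, -0.2)
  mk_traj <- function(theta, t_fall) structure(
    list(time = t[seq_len(nrow(theta))], theta = theta, t_fall = t_fall),
    class = "stance_trajectory")
  # stood the whole horizon at the initial pose: J exactly 0
  thA <- matrix(rep(th0, each = length(t)), ncol = 2)
  jA <- objective_J(mk_traj(thA, 5000))
  expect_equal(jA$J_fail, 0)
  expect_equal(jA$J_pos, 0)
  expect_equal(jA$J, 0)
  # fall halfway: J_fail = (5000 - 2500) / 2500 = 1
  thB <- thA[t <= 2.5, , drop = FALSE]
  jB <- objective_J(mk_traj(thB, 2500))
  expect_equal(jB$J_fail, 1)
  expect_equal(jB$J, 10000)
  # immediate fall guarded by the large sentinel
  expect_equal(objective_J(mk_traj(thA[1:2, , drop = FALSE], 0))$J_fail, 1e9)
  # constant deviation of 0.1 rad on one joint over 5 s -> J_pos = 0.5
  thC <- thA; thC[, 1] <- th0[1] + 0.1
  thC[1, 1] <- th0[1]  # initial pose taken from the first sample
  jC <- objective_J(mk_traj(thC, 5000))
  expect_equal(jC$J_pos, 0.1 * 5, tolerance = 1e-3)
  expect_gt(jC$J, 0)
})

test_that("CMA-ES minimizes standard test functions deterministically", {
  sphere <- function(x) sum(x^2)
  cfg <- cma_config(lambda = 10, sigma = 0.3, max_iter = 200, seed = 7,
                    lower = -Inf, upper = Inf)
  r1 <- cma_es(sphere, c(1, -1, 0.5), cfg)
  expect_lt(r1$value, 1e-10)
  # deterministic for a fixed seed
  r2 <- cma_es(sphere, c(1, -1, 0.5), cfg)
  expect_identical(r1$value, r2$value)
  expect_identical(r1$par, r2$par)
  # best-so-far is monotone nonincreasing
  expect_true(all(diff(r1$history$best) <= 0))
  # Rosenbrock in 4d from a seeded start
  rosen <- function(x) sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
  r3 <- cma_es(rosen, rep(0, 4),
               cma_config(lambda = 12, sigma = 0.3, max_iter = 600, seed = 1,
                          lower = -Inf, upper = Inf))
  expect_lt(r3$value, 1e-6)
  # reflection keeps iterates inside the box
  boxed <- cma_es(function(x) sum((x - 0.2)^2),
                  c(0.5, 0.5),
                  cma_config(lambda = 8, sigma = 0.2, max_iter = 100,
                             seed = 3, lower = 0, upper = 1))
  expect_true(all(boxed$par >= 0 & boxed$par <= 1))
  expect_lt(boxed$value, 1e-8)
  # ftarget stops the search early
  r4 <- cma_es(sphere, c(1, 1),
               cma_config(lambda = 8, sigma = 0.3, max_iter = 500, seed = 2,
                          lower = -Inf, upper = Inf, ftarget = 1e-4))
  expect_lte(r4$value, 1e-4)
  expect_lt(nrow(r4$history), 500)
})

test_that("gain optimization on the muscle-driven pendulum finds standing gains", {
  fx <- make_fixture("single_link")
  cands <- sweep_uff_candidates(fx$config, fx$muscles,
                                P_values = c(2, 3), D_values = c(2, 3),
                                T_simu = 3000, window = c(1500, 3000))
  expect_gt(length(cands), 0)
  res <- optimize_gains(fx$config, fx$muscles, cands[[1]], 270,
                        cma = cma_config(lambda = 8, sigma = 0.005,
                                         max_iter = 50, seed = 42),
                        objective = objective_config(T_simu = 3000),
                        stop_on_stand = TRUE)
  expect_equal(res$J_fail, 0)
  expect_true(res$converged)
  expect_true(all(c(res$k_p, res$k_d) >= 0))
})
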