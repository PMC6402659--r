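two_link <- function(damping = c(0, 0))
  plant_config(links = data.frame(mass = c(5, 3), length = c(0.6, 0.5),
                                  com = c(0.3, 0.25),
                                  inertia = c(0.15, 0.0625)),
               joints = c("a", "b"), initial_pose = c(0, 0),
               joint_damping = damping)

test_that("muscle torques sum force times moment arm per joint", {
  ms <- muscle_set(
    muscle("m1", F0 = 1, L_opt = 0.1, L_slack = 0.1, L_ref = 0.3, V_max = 1,
           moment_arms = c(0.05, 0), group = "g"),
    muscle("m2", F0 = 1, L_opt = 0.1, L_slack = 0.1, L_ref = 0.3, V_max = 1,
           moment_arms = c(-0.05, 0.02), group = "g"))
  expect_equal(joint_torques_from_muscles(c(100, 0), ms), c(5, 0))
  expect_equal(joint_torques_from_muscles(c(100, 100), ms), c(0, 2))
  # independent brute-force oracle on a random case
  set.seed(7)
  F <- runif(2, 0, 500)
  ma <- rbind(c(0.05, 0), c(-0.05, 0.02))
  oracle <- c(sum(F * ma[, 1]), sum(F * ma[, 2]))
  expect_equal(joint_torques_from_muscles(F, ms), oracle)
  expect_error(joint_torques_from_muscles(1, ms), "count")
})

test_that("chain dynamics reproduce pendulum closed forms", {
  # single link, point mass m at length l (inertia negligible)
  cfg <- plant_config(links = data.frame(mass = 2, length = 1, com = 1,
                                         inertia = 1e-12),
                      joints = "j")
  expect_equal(plant_dynamics(cfg, 0, 0, 0, 0), 0)  # upright equilibrium
  expect_equal(plant_dynamics(cfg, 0.3, 0, 0, 0), 9.80665 * sin(0.3),
               tolerance = 1e-9)
  # upright link under base acceleration A: thetaddot = -A / l
  expect_equal(plant_dynamics(cfg, 0, 0, 0, 2), -2, tolerance = 1e-9)
  # applied torque: thetaddot = tau / (m l^2)
  expect_equal(plant_dynamics(cfg, 0, 0, 0.5, 0), 0.5 / 2, tolerance = 1e-9)
})

test_that("centre-of-mass height matches the mass-weighted oracle", {
  cfg1 <- plant_config(links = data.frame(mass = 1, length = 1, com = 0.5,
                                          inertia = 0.1), joints = "j")
  expect_equal(com_height(cfg1, 0), 0.5)
  expect_equal(com_height(cfg1, pi / 2), 0, tolerance = 1e-12)
  cfg2 <- two_link()
  th <- c(0.4, -0.7)
  z1 <- 0.3 * cos(0.4)
  z2 <- 0.6 * cos(0.4) + 0.25 * cos(0.4 - 0.7)
  expect_equal(com_height(cfg2, th), (5 * z1 + 3 * z2) / 8)
})

test_that("passive conservative chain conserves energy to 0.1% over 5 s", {
  cfg <- two_link()
  pe <- posturesim:::plant_energy
  th <- c(0.4, -0.3); thd <- c(0, 0)
  e0 <- pe(cfg, th, thd)
  for (i in 1:5000) {
    s <- plant_step(cfg, th, thd, c(0, 0), 0, 0.001)
    th <- s$theta; thd <- s$theta_dot
  }
  expect_lt(abs(pe(cfg, th, thd) - e0) / abs(e0), 0.001)
})

test_that("plant step is stationary without forcing and converges at 4th order", {
  cfg <- plant_config(links = data.frame(mass = 1, length = 1, com = 0.5,
                                         inertia = 0.1),
                      joints = "j", gravity = 0)
  s <- plant_step(cfg, 0.3, 0, 0, 0, 0.001)
  expect_equal(s$theta, 0.3)
  expect_equal(s$theta_dot, 0)
  # step-halving on a passive pendulum: error ratio ~ 2^4
  cfgp <- plant_config(links = data.frame(mass = 1, length = 1, com = 0.5,
                                          inertia = 0.1), joints = "j")
  run <- function(dt, T = 0.5) {
    th <- 0.3; thd <- 0
    for (i in seq_len(round(T / dt))) {
      s <- plant_step(cfgp, th, thd, 0, 0, dt)
      th <- s$theta; thd <- s$theta_dot
    }
    th
  }
  ref <- run(0.0001)
  e1 <- abs(run(0.001) - ref)
  e2 <- abs(run(0.0005) - ref)
  expect_gt(e1 / e2, 10)  # ~16 for a 4th-order scheme
})

test_that("fall detection returns the first crossing time in ms", {
  traj <- list(time = seq(0, 5, by = 0.001),
               com_height = rep(1, 5001))
  expect_equal(detect_fall(traj, 0.9), 5000)
  h <- rep(1, 5001); h[2501:5001] <- 0.8
  expect_equal(detect_fall(list(time = seq(0, 5, by = 0.001),
                                com_height = h), 0.9), 2500)
  expect_equal(detect_fall(list(time = c(0, 0.001),
                                com_height = c(0.5, 0.5)), 0.9), 0)
  expect_error(detect_fall(list(time = numeric(), com_height = numeric()),
                           0.9), "empty")
})

test_that("unactuated inverted pendulum falls and is detected", {
  # bare pendulum with slack muscles (never reach the passive region)
  config <- plant_config(links = data.frame(mass = 72, length = 1.6,
                                            com = 0.914, inertia = 8),
                         joints = "ankle", initial_pose = 0.02)
  ms <- muscle_set(
    muscle("ext", F0 = 100, L_opt = 0.2, L_slack = 0.01, L_ref = 0.1,
           V_max = 1, moment_arms = -0.05, group = "ankle_extensor"),
    muscle("flx", F0 = 100, L_opt = 0.2, L_slack = 0.01, L_ref = 0.1,
           V_max = 1, moment_arms = 0.05, group = "ankle_flexor"))
  ctrl <- controller_params(u_ff = c(0, 0),
                            k_p = c(ankle_extensor = 0, ankle_flexor = 0),
                            k_d = c(ankle_extensor = 0, ankle_flexor = 0),
                            group_map = c("ankle_extensor", "ankle_flexor"),
                            u_clip = c(1e-9, 1))
  tr <- simulate_stance(config, ms, ctrl, T_simu = 5000)
  expect_false(tr$stood)
  expect_equal(tr$status, "fell")
  expect_lt(tr$t_fall, 5000)
})
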