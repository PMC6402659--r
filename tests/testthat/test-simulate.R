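test_that("compiled and reference engines agree to machine precision", {
  fx <- make_fixture("sagittal_3link")
  pert <- perturbation_spec(direction_deg = 270, onset = 50)
  t_cpp <- simulate_stance(fx$config, fx$muscles, fx$controller, pert,
                           T_simu = 300)
  t_ref <- simulate_stance(fx$config, fx$muscles, fx$controller, pert,
                           T_simu = 300, engine = "R")
  expect_equal(t_cpp$theta, t_ref$theta, tolerance = 1e-12)
  expect_equal(t_cpp$activations, t_ref$activations, tolerance = 1e-12)
  expect_equal(t_cpp$controls, t_ref$controls, tolerance = 1e-12)
  expect_equal(t_cpp$com_height, t_ref$com_height, tolerance = 1e-12)
})

test_that("identical configurations give bit-identical trajectories", {
  fx <- make_fixture("sagittal_3link")
  pert <- perturbation_spec(direction_deg = 30)
  a <- simulate_stance(fx$config, fx$muscles, fx$controller, pert,
                       T_simu = 800)
  b <- simulate_stance(fx$config, fx$muscles, fx$controller, pert,
                       T_simu = 800)
  expect_identical(a$theta, b$theta)
  expect_identical(a$activations, b$activations)
})

test_that("mirrored perturbations mirror the frontal plant's responses", {
  fx <- make_fixture("frontal_2link")
  gm <- vapply(fx$muscles, function(m) m$group, "")
  # identical gains across each antagonist pair: the mirror property
  # requires a left-right symmetric controller
  k_p <- c(subtalar_evertor = 1.0, subtalar_invertor = 1.0,
           hip_abductor = 1.0, hip_adductor = 1.0)
  k_d <- c(subtalar_evertor = 0.2, subtalar_invertor = 0.2,
           hip_abductor = 0.3, hip_adductor = 0.3)
  ctrl <- controller_params(u_ff = rep(0, 4), k_p = k_p, k_d = k_d,
                            group_map = gm)
  right <- simulate_stance(fx$config, fx$muscles, ctrl,
                           perturbation_spec(direction_deg = 0, onset = 100),
                           T_simu = 1200)
  left <- simulate_stance(fx$config, fx$muscles, ctrl,
                          perturbation_spec(direction_deg = 180, onset = 100),
                          T_simu = 1200)
  # joint angles mirror, and the evertor/invertor (and ab/adductor)
  # activation traces swap
  expect_equal(right$theta, -left$theta, tolerance = 1e-10)
  expect_equal(right$activations[, "subtalar_evertor"],
               unname(left$activations[, "subtalar_invertor"]),
               tolerance = 1e-10)
  expect_equal(right$activations[, "hip_abductor"],
               unname(left$activations[, "hip_adductor"]),
               tolerance = 1e-10)
})

test_that("activation responds to a kinematic event after exactly the loop delays", {
  # gravity-free symmetric pair: a true equilibrium until the platform
  # moves, so every later signal change is attributable to the pulse
  config <- plant_config(links = data.frame(mass = 10, length = 1,
                                            com = 0.5, inertia = 1),
                         joints = "j", gravity = 0, initial_pose = 0)
  ms <- muscle_set(
    muscle("ext", F0 = 1000, L_opt = 0.06, L_slack = 0.04, L_ref = 0.0988,
           V_max = 0.4, moment_arms = -0.05, group = "ankle_extensor"),
    muscle("flx", F0 = 1000, L_opt = 0.06, L_slack = 0.04, L_ref = 0.0988,
           V_max = 0.4, moment_arms = 0.05, group = "ankle_flexor"))
  bg <- base_gains(gain_ratio_table(), 1, 1)
  grp <- c("ankle_extensor", "ankle_flexor")
  ctrl <- controller_params(u_ff = c(0.5, 0.5), k_p = bg$k_p[grp],
                            k_d = bg$k_d[grp], group_map = grp)
  onset <- 200
  tr <- simulate_stance(config, ms, ctrl,
                        perturbation_spec(direction_deg = 90, onset = onset,
                                          distance = 1, duration = 100),
                        T_simu = 600)
  t_ms <- tr$time * 1000
  first_change <- function(x)
    t_ms[which(rowSums(abs(sweep(x, 2, x[1, ]))) > 1e-15)[1]]
  first_L <- first_change(tr$L_MT)
  first_u <- first_change(tr$controls)
  first_a <- first_change(tr$activations)
  expect_equal(first_L, onset + 1)        # platform acts within one step
  expect_equal(first_u - first_L, 40)     # feedback delay, exact on grid
  # activation dynamics read the control tau_trans later; the state first
  # differs one integration step after that
  expect_equal(first_a - first_u, 40 + 1)
})

test_that("zero-delay runs reduce to an undelayed PD loop", {
  fx <- make_fixture("single_link")
  gm <- vapply(fx$muscles, function(m) m$group, "")
  bg <- base_gains(gain_ratio_table(), 2, 2)
  ctrl0 <- controller_params(u_ff = rep(0, 2), k_p = bg$k_p[unique(gm)],
                             k_d = bg$k_d[unique(gm)], group_map = gm,
                             tau_fb = 0, tau_trans = 0)
  tr <- simulate_stance(fx$config, fx$muscles, ctrl0, T_simu = 400)
  # the undelayed control at each step equals the PD law applied to the
  # instantaneous kinematics
  gains <- posturesim:::expand_gains(ctrl0)
  mm <- posturesim:::muscle_matrices(fx$muscles)
  k <- 151
  u_fb <- gains$kp * (tr$L_MT[k, ] - tr$L0_MT) / tr$L0_MT +
    gains$kd * tr$Ldot_MT[k, ] / mm$V_max
  expect_equal(tr$controls[k, ],
               pmin(pmax(u_fb, 0.001), 1), tolerance = 1e-12)
})

test_that("trajectories convert to tidy data frames", {
  fx <- make_fixture("single_link")
  tr <- simulate_stance(fx$config, fx$muscles, fx$controller, T_simu = 40)
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 41)
  expect_true(all(c("time", "base_pos", "com_height", "theta_ankle",
                    "a_ankle_flexor", "u_ankle_extensor",
                    "L_ankle_extensor") %in% names(df)))
})
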