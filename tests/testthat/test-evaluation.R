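test_that("baseline activation averages the 50-150 ms pre-onset window", {
  t_ms <- seq(0, 1000, by = 1)
  expect_equal(baseline_activation(rep(0.2, 1001), t_ms, 500), 0.2)
  step <- ifelse(t_ms < 500, 0.2, 0.5)
  expect_equal(baseline_activation(step, t_ms, 500), 0.2)
  # sampled ramp: mean of a linear function over [350, 450] is its midpoint
  ramp <- 0.001 * t_ms
  expect_equal(baseline_activation(ramp, t_ms, 500), 0.001 * 400)
  expect_error(baseline_activation(rep(0.2, 51), seq(460, 510), 500),
               "window")
})

test_that("integrated response is the baseline-subtracted integral in seconds", {
  t_ms <- seq(0, 1000, by = 1)
  base <- rep(0.2, 1001)
  expect_equal(integrated_response(base, t_ms, 500, 0.2), 0)
  # constant offset 0.05 over the 200 ms window -> 0.01 s
  expect_equal(integrated_response(base + 0.05, t_ms, 500, 0.2), 0.01)
  # half-sine bump of known area placed inside the window
  syn <- synth_activation_traces(directions = 90, preferred_deg = 90,
                                 peak_area = 0.01, baseline = 0.1,
                                 onset = 500)
  got <- integrated_response(syn$traces[, 1], syn$time_ms, 500, 0.1)
  expect_equal(got, 0.01, tolerance = 1e-9)
  # below-baseline activity integrates negative
  expect_lt(integrated_response(base - 0.05, t_ms, 500, 0.2), 0)
})

test_that("unit-max normalization maps the peak to one and is scale invariant", {
  v <- c(1, 3, 7.3, 2, 0.5, 1, 1, 1, 1, 1, 1, 1)
  n <- normalize_unit_max(v)
  expect_equal(max(n), 1)
  expect_equal(which.max(n), 3)
  expect_equal(as.numeric(normalize_unit_max(10 * v)), as.numeric(n))
  expect_equal(as.numeric(normalize_unit_max(rep(2, 12))), rep(1, 12))
  neg <- c(-1, 2, 4, rep(1, 9))
  nn <- normalize_unit_max(neg)
  expect_equal(nn[1], 0)               # negative entries clipped
  expect_equal(attr(nn, "n_clipped"), 1L)
  expect_error(normalize_unit_max(rep(-1, 12)), "degenerate")
})

test_that("signed normalization is an affine map onto [-1, 1]", {
  v <- c(0.3, -0.2, 0.8, 0.1, rep(0, 8))
  n <- normalize_signed(v)
  expect_equal(min(n), -1)
  expect_equal(max(n), 1)
  expect_equal(n[which.min(v)], -1)
  expect_equal(n[which.max(v)], 1)
  # invariant to positive affine transforms of the input
  expect_equal(normalize_signed(3 * v + 7), n)
  expect_error(normalize_signed(rep(1, 12)), "degenerate")
  sym <- c(-2, 0, 2)
  expect_equal(normalize_signed(sym)[2], 0)
})

test_that("cosine similarity has the expected geometry", {
  v <- c(1, 2, -1, 0.5, rep(0.1, 8))
  expect_equal(cosine_similarity(v, v), 1)
  expect_equal(cosine_similarity(v, -v), -1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(v, 5 * v), 1)  # scale invariance
  expect_error(cosine_similarity(v, rep(0, 12)), "zero")
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(12)
    s <- cosine_similarity(a, b)
    expect_true(s >= -1 && s <= 1)
  }
})

test_that("the Monte-Carlo similarity null is centred with std near 1/sqrt(12)", {
  v_ref <- c(0.9, -0.3, 0.7, 0.1, -1, 0.4, 0.2, -0.6, 0.8, 0, 0.5, -0.2)
  null <- random_similarity_null(v_ref, n = 20000, seed = 11)
  expect_lt(abs(null$mean), 3 * null$sd / sqrt(null$n))
  expect_equal(null$sd, 1 / sqrt(12), tolerance = 0.02)
  with_obs <- random_similarity_null(v_ref, n = 5000, seed = 11,
                                     observed = 0)
  expect_equal(
    with_obs$cumulative_prob,
    stats::pnorm(0, with_obs$mean, with_obs$sd))
  at_mean <- random_similarity_null(v_ref, n = 5000, seed = 2,
                                    observed = NULL)
  expect_equal(stats::pnorm(at_mean$mean, at_mean$mean, at_mean$sd), 0.5)
})

test_that("response profiles recover constructed cosine tuning", {
  syn <- synth_activation_traces(preferred_deg = 90, peak_area = 0.01,
                                 baseline = 0.1, onset = 500)
  # wrap the synthetic traces as minimal trajectory objects
  trajs <- lapply(seq_along(syn$directions), function(k) {
    structure(list(time = syn$time_ms / 1000,
                   activations = matrix(syn$traces[, k], ncol = 1,
                                        dimnames = list(NULL, "m1")),
                   muscles = "m1",
                   perturbation = perturbation_spec(
                     direction_deg = syn$directions[k])),
              class = "stance_trajectory")
  })
  prof <- response_profile(trajs, syn$directions)
  expect_equal(as.numeric(prof$integrated[, 1]), unname(syn$areas),
               tolerance = 1e-8)
  expect_equal(unname(which.max(prof$normalized_01[, 1])),
               which(syn$directions == 90))
  # the profile matches its own generating tuning almost perfectly
  s <- cosine_similarity(normalize_signed(prof$integrated[, 1]),
                         normalize_signed(syn$areas))
  expect_gt(s, 0.99)
})

test_that("passive torque matches a single-muscle hand computation", {
  fx <- make_fixture("single_link")
  ctrl <- fx$controller
  tr <- simulate_stance(fx$config, fx$muscles, ctrl,
                        perturbation_spec(direction_deg = 270),
                        T_simu = 700)
  u_ff <- c(0.3, 0)   # only the extensor carries feed-forward tone
  pt <- passive_torque(tr, fx$muscles, u_ff)
  expect_equal(nrow(pt), 71)
  # hand computation at the 30th sample
  k <- which(tr$time * 1000 >= 500)[1] + 29
  cv <- hill_curves()
  mm <- posturesim:::muscle_matrices(fx$muscles)
  Tq <- 0
  for (i in 1:2) {
    l <- (tr$L_MT[k, i] - mm$L_slack[i]) / mm$L_opt[i]
    v <- tr$Ldot_MT[k, i] / mm$V_max[i]
    F <- mm$F0[i] * (u_ff[i] * active_force_length(l, cv) *
                       force_velocity(v, cv) + passive_force_length(l, cv))
    Tq <- Tq + F * mm$ma[i, 1]
  }
  expect_equal(pt$torque[30], unname(-Tq), tolerance = 1e-10)
  # linear in F0: doubling all strengths doubles the torque
  ms2 <- muscle_set(lapply(fx$muscles, function(m) {
    m$F0 <- 2 * m$F0; m
  }))
  pt2 <- passive_torque(tr, ms2, u_ff)
  expect_equal(pt2$torque, 2 * pt$torque, tolerance = 1e-10)
})

test_that("relative stiffness converts per-degree stiffness against mgh", {
  # critical stiffness expressed per degree gives exactly 1
  K_crit_deg <- (72 * 9.80665 * 0.914 / 2) * pi / 180
  expect_equal(relative_stiffness(K_crit_deg, 72, 9.80665, 0.914), 1)
  # agreement with the printed three-decimal value
  expect_equal(round(relative_stiffness(1.17, 72.0, 9.80665, 0.914), 3),
               0.208)
})
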