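#' Built-in study plants
#'
#' Deterministic desk-scale plants with antagonist muscle pairs, anchored to
#' full-scale anthropometry (total mass 72 kg at `scale = 1`, and for the
#' single-link plant an upright CoM height of 0.914 m above the ankle):
#'
#' * `"single_link"`: one ankle joint, two muscles — the classic
#'   muscle-driven inverted pendulum.
#' * `"sagittal_3link"`: ankle-knee-hip/lumbar pitch chain, three antagonist
#'   pairs plus one biarticular (gastrocnemius-like) muscle (7 muscles).
#' * `"frontal_2link"`: subtalar inversion/eversion and hip
#'   ab/adduction-plus-lumbar-bend roll chain, two antagonist pairs,
#'   left-right symmetric.
#'
#' Muscle paths are laid out so that every muscle sits just below its
#' optimal fiber length (normalized length 0.98) in the configured initial
#' pose: passive elastic force is disengaged at rest and recruits only on
#' stretch, so resting joint impedance is set by activation-dependent
#' muscle properties rather than by passive springs.
#'
#' Geometric quantities scale linearly with `scale`, masses with its cube,
#' inertias with its fifth power, and muscle strengths with its square.
#'
#' @param name Fixture name.
#' @param scale Anthropometry scale (default 1).
#' @return A list with `config` (a [plant_config()]), `muscles` (a
#'   [muscle_set()]) and `controller` (a [controller_params()] skeleton with
#'   zero feed-forward and unit-sweep base gains).
#' @examples
#' fx <- make_fixture("single_link")
#' com_height(fx$config, fx$config$initial_pose)
#' @export
make_fixture <- function(name = c("single_link", "sagittal_3link",
                                  "frontal_2link"), scale = 1) {
  name <- match.arg(name)
  stopifnot(scale > 0)
  s <- scale
  L_opt <- 0.06 * s
  L_slack <- 0.04 * s
  l0 <- 0.98                      # normalized fiber length at initial pose

  if (name == "single_link") {
    pose <- 0.02
    config <- plant_config(
      links = data.frame(mass = 72 * s^3, length = 1.60 * s,
                         com = 0.914 * s, inertia = 8.0 * s^5),
      joints = "ankle", plane = "sagittal",
      initial_pose = pose, joint_damping = 2.0 * s^4)
    arms <- list(ankle_extensor = c(-0.12), ankle_flexor = c(0.10))
    F0 <- c(ankle_extensor = 16000, ankle_flexor = 8000)
    groups <- c(ankle_extensor = "ankle_extensor",
                ankle_flexor = "ankle_flexor")
  } else if (name == "sagittal_3link") {
    pose <- c(0.06, -0.12, 0.12)
    config <- plant_config(
      links = data.frame(
        mass = c(7, 14, 51) * s^3,
        length = c(0.43, 0.45, 0.85) * s,
        com = c(0.25, 0.25, 0.19) * s,
        inertia = c(0.06, 0.12, 2.60) * s^5),
      joints = c("ankle", "knee", "hip"), plane = "sagittal",
      initial_pose = pose, joint_damping = c(2, 2, 4) * s^4)
    arms <- list(ankle_extensor = c(-0.12, 0, 0),
                 ankle_flexor = c(0.10, 0, 0),
                 knee_extensor = c(0, -0.10, 0),
                 knee_flexor = c(0, 0.08, 0),
                 hip_extensor = c(0, 0, -0.11),
                 hip_flexor = c(0, 0, 0.09),
                 gastrocnemius = c(-0.07, 0.05, 0))
    F0 <- c(ankle_extensor = 16000, ankle_flexor = 8000,
            knee_extensor = 12000, knee_flexor = 8000,
            hip_extensor = 14000, hip_flexor = 10000,
            gastrocnemius = 8000)
    groups <- c(ankle_extensor = "ankle_extensor",
                ankle_flexor = "ankle_flexor",
                knee_extensor = "knee_extensor",
                knee_flexor = "knee_flexor",
                hip_extensor = "hip_extensor",
                hip_flexor = "hip_flexor",
                gastrocnemius = "biarticular")
  } else {
    pose <- c(0, 0)
    config <- plant_config(
      links = data.frame(
        mass = c(24, 48) * s^3,
        length = c(0.90, 0.85) * s,
        com = c(0.50, 0.32) * s,
        inertia = c(1.40, 2.60) * s^5),
      joints = c("subtalar", "hip_roll"), plane = "frontal",
      initial_pose = pose, joint_damping = c(2, 4) * s^4)
    arms <- list(subtalar_evertor = c(0.07, 0),
                 subtalar_invertor = c(-0.07, 0),
                 hip_abductor = c(0, 0.08),
                 hip_adductor = c(0, -0.08))
    F0 <- c(subtalar_evertor = 9000, subtalar_invertor = 9000,
            hip_abductor = 10000, hip_adductor = 10000)
    groups <- c(subtalar_evertor = "subtalar_evertor",
                subtalar_invertor = "subtalar_invertor",
                hip_abductor = "hip_abductor",
                hip_adductor = "hip_adductor")
  }

  muscles <- muscle_set(lapply(names(arms), function(nm) {
    ma <- arms[[nm]] * s
    muscle(nm, F0 = F0[[nm]] * s^2, L_opt = L_opt, L_slack = L_slack,
           # place the fiber at l0 in the initial pose
           L_ref = L_slack + l0 * L_opt + sum(ma * pose),
           V_max = 0.4 * s, moment_arms = ma, group = groups[[nm]])
  }))

  mm <- muscle_matrices(muscles)
  table <- gain_ratio_table(frontal_analogs = (name == "frontal_2link"))
  bg <- base_gains(table, 1, 1)
  grp <- mm$group
  controller <- controller_params(
    u_ff = rep(0, length(muscles)),
    k_p = bg$k_p[unique(grp)], k_d = bg$k_d[unique(grp)],
    group_map = grp)
  list(config = config, muscles = muscles, controller = controller)
}
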