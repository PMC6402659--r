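#' Write controller parameters to JSON
#'
#' Lossless round-trip serialization of a [controller_params()] object.
#'
#' @param params A `controller_params` object.
#' @param path Output file.
#' @export
write_controller <- function(params, path) {
  obj <- list(u_ff = params$u_ff,
              k_p = as.list(params$k_p), k_d = as.list(params$k_d),
              group_map = params$group_map,
              tau_fb = params$tau_fb, tau_trans = params$tau_trans,
              L0_MT = params$L0_MT, u_clip = params$u_clip)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_controller
#' @return `read_controller` returns the deserialized
#'   [controller_params()] object.
#' @export
read_controller <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  controller_params(u_ff = as.numeric(obj$u_ff),
                    k_p = unlist(obj$k_p), k_d = unlist(obj$k_d),
                    group_map = as.character(obj$group_map),
                    tau_fb = obj$tau_fb, tau_trans = obj$tau_trans,
                    L0_MT = if (is.null(obj$L0_MT)) NULL
                            else as.numeric(obj$L0_MT),
                    u_clip = as.numeric(obj$u_clip))
}

#' Write a trajectory as tidy CSV with a JSON metadata sidecar
#'
#' One row per time step (time, joint angles, base position, CoM height,
#' per-muscle activation/control/length).  The sidecar (`<path>.meta.json`)
#' records the outcome, fall time, step, horizon, feed-forward norm, a
#' configuration hash, and an optional seed, so runs are reproducible from
#' their metadata.
#'
#' @param traj A `stance_trajectory`.
#' @param path CSV output file.
#' @param seed Optional integer recorded in the sidecar.
#' @export
write_trajectory <- function(traj, path, seed = NULL) {
  df <- as.data.frame(traj)
  utils::write.csv(df, path, row.names = FALSE)
  cfg_string <- paste(
    deparse(traj$config[c("links", "joints", "plane", "gravity",
                          "initial_pose")]),
    deparse(traj$controller[c("u_ff", "k_p", "k_d", "tau_fb", "tau_trans")]),
    collapse = "")
  meta <- list(status = traj$status, stood = traj$stood,
               t_fall_ms = traj$t_fall, dt = traj$dt, T_simu = traj$T_simu,
               uff_norm_sq = traj$uff_norm_sq,
               fall_threshold_m = traj$fall_threshold,
               config_hash = sprintf("%08x", sum(utf8ToInt(cfg_string) *
                                                   seq_along(utf8ToInt(cfg_string))) %% 0xFFFFFFFF),
               seed = seed,
               perturbation = if (is.null(traj$perturbation)) NULL else
                 unclass(traj$perturbation))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @return `read_trajectory_csv` returns the data frame with the metadata
#'   attached as attribute `"meta"`.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path))
    attr(df, "meta") <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df
}

#' Write a response profile as CSV
#'
#' @param profile A `response_profile`.
#' @param path Output CSV.
#' @export
write_response_profile <- function(profile, path) {
  df <- data.frame(direction_deg = profile$directions)
  for (m in profile$muscles) {
    df[[paste0("integrated_", m)]] <- profile$integrated[, m]
    df[[paste0("norm01_", m)]] <- profile$normalized_01[, m]
    df[[paste0("signed_", m)]] <- profile$normalized_signed[, m]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read reference 12-direction response vectors
#'
#' Reads a CSV with a `direction_deg` column and one column per muscle
#' giving the reference (e.g. experimentally measured) tuning values.
#'
#' @param path CSV file with 12 rows.
#' @return Data frame ordered by direction.
#' @export
read_response_reference <- function(path) {
  df <- utils::read.csv(path)
  if (!"direction_deg" %in% names(df))
    stop("reference CSV must have a direction_deg column")
  if (nrow(df) != 12)
    stop("reference CSV must have 12 rows (one per direction)")
  df[order(df$direction_deg), , drop = FALSE]
}
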