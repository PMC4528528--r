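#' Read and write trajectory files
#'
#' Plain-text CSV, one row per detection, header
#' `frame,point_id,x,y,valid`; `x`, `y` are in whatever source frame the
#' trial manifest names (camera plane before rectification, arena frame
#' after). This dialect is also the import target for converted output of
#' tracking software.
#'
#' @param path File path.
#' @param fps,duration_s Frame rate and trial duration attached to the
#'   trajectory.
#' @param traj A [trajectory()] to write.
#' @return `read_trajectory()` returns a [trajectory()];
#'   `write_trajectory()` returns `path` invisibly.
#' @export
read_trajectory <- function(path, fps = 30, duration_s = 1200) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("frame", "point_id", "x", "y", "valid") %in% names(df)))
  df$valid <- as.logical(df$valid)
  if ("at_object" %in% names(df)) df$at_object <- as.logical(df$at_object)
  trajectory(df, fps = fps, duration_s = duration_s)
}

#' @rdname read_trajectory
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "shoal_traj"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write inspection event logs
#'
#' Plain-text CSV with header `start_s,end_s,group_size`, one row per scored
#' inspection.
#'
#' @param path File path.
#' @param events Event tibble to write.
#' @return `read_events()` returns a tibble; `write_events()` returns `path`
#'   invisibly.
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("start_s", "end_s", "group_size") %in% names(df)))
  tibble::as_tibble(df)
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("start_s", "end_s", "group_size")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write trial manifests
#'
#' One YAML manifest per trial: identifiers and factors (sex, brain size,
#' replicate, shoal size, stimulus), frame rate and duration, camera-corner
#' correspondences, the measured object pose, and mask-region definitions.
#'
#' @param path Manifest path.
#' @param manifest Named list to write.
#' @return `read_manifest()` returns a named list with `pose` rebuilt as an
#'   [object_pose()] and `corners` as a tibble when present.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  if (!is.null(m$pose)) {
    m$pose <- object_pose(m$pose$x_cm, m$pose$y_cm,
                          ifelse(is.null(m$pose$heading_deg), NA_real_, m$pose$heading_deg),
                          kind = m$pose$kind %||% "predator_model")
  }
  if (!is.null(m$corners)) {
    m$corners <- tibble::as_tibble(lapply(m$corners, unlist))
  }
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  if (inherits(manifest$pose, "object_pose")) {
    p <- manifest$pose
    manifest$pose <- list(x_cm = p$x_cm, y_cm = p$y_cm,
                          heading_deg = if (is.na(p$heading_deg)) NULL else p$heading_deg,
                          kind = p$kind)
  }
  if (is.data.frame(manifest$corners)) {
    manifest$corners <- as.list(as.data.frame(manifest$corners))
  }
  yaml::write_yaml(manifest, path)
  invisible(path)
}

write_trial <- function(trial, stem, arena, fps, duration_s) {
  degraded <- apply_camera(trial$trajectory, arena = arena)
  paths <- list(trajectory = paste0(stem, "_trajectory.csv"),
                events = paste0(stem, "_events.csv"),
                manifest = paste0(stem, "_manifest.yaml"),
                truth = paste0(stem, "_truth.csv"))
  write_trajectory(degraded$trajectory, paths$trajectory)
  write_events(trial$events, paths$events)
  write_trajectory(trial$trajectory, paths$truth)
  manifest <- c(as.list(trial$info),
                list(fps = fps, duration_s = duration_s,
                     seed = trial$seed, pose = trial$pose,
                     corners = degraded$corners,
                     params = unclass(trial$params)))
  write_manifest(manifest, paths$manifest)
  paths
}

#' Read one simulated/converted trial from disk
#'
#' @param stem Path stem as produced by [simulate_study()] (files
#'   `<stem>_trajectory.csv`, `<stem>_events.csv`, `<stem>_manifest.yaml`).
#' @return A list with `trajectory`, `events`, `manifest`.
#' @export
read_trial <- function(stem) {
  manifest <- read_manifest(paste0(stem, "_manifest.yaml"))
  list(
    trajectory = read_trajectory(paste0(stem, "_trajectory.csv"),
                                 fps = manifest$fps %||% 30,
                                 duration_s = manifest$duration_s %||% 1200),
    events = read_events(paste0(stem, "_events.csv")),
    manifest = manifest
  )
}

#' Serialise grid maps
#'
#' Writes a density or significance map as a plain matrix CSV (rows = y
#' cells, columns = x cells) plus a JSON sidecar holding the grid
#' specification and test metadata.
#'
#' @param map A `density_map` or `significance_map`.
#' @param stem Output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @param field Which column to rasterise (default `"density"` or `"p"`).
#' @return `stem`, invisibly.
#' @export
write_map <- function(map, stem, field = NULL) {
  grid <- attr(map, "grid")
  if (is.null(field)) field <- if ("density" %in% names(map)) "density" else "p"
  M <- matrix(map[[field]][order(map$iy, map$ix)], nrow = grid$n_y,
              ncol = grid$n_x, byrow = TRUE)
  utils::write.table(M, paste0(stem, ".csv"), sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(field = field,
               n_x = grid$n_x, n_y = grid$n_y, cell_cm = grid$cell_cm,
               arena = list(length_cm = grid$arena$length_cm,
                            width_cm = grid$arena$width_cm),
               test_kind = attr(map, "test_kind"),
               n_valid_obs = attr(map, "n_valid_obs"))
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE, null = "null")
  invisible(stem)
}
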