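#' Camera/acquisition parameters for the synthetic study generator
#'
#' Describes how a ground-truth trial is degraded into what tracking software
#' would deliver: a perspective distortion (the inverse of the rectifying
#' homography), occlusion regions whose observations are lost, and optional
#' jitter applied to the stimulus pose when trials are generated.
#'
#' @param homography The camera-to-arena rectifying `homography`; positions
#'   are pushed through its inverse. Default: a mild oblique view
#'   ([tilted_view_homography()]).
#' @param occlusion_regions List of [mask_region()]s. Regions with policy
#'   `"missing"` (the ledge) delete observations outright; regions with
#'   policy `"lowest_bin_for_distance"` (over the object) delete coordinates
#'   but keep an at-object record.
#' @param object_jitter_cm,object_jitter_deg Per-trial sd of stimulus
#'   placement jitter (position, heading) applied when a study draws trial
#'   poses.
#' @return An object of class `camera_params`.
#' @export
camera_params <- function(homography = tilted_view_homography(),
                          occlusion_regions = list(),
                          object_jitter_cm = 0.8, object_jitter_deg = 5) {
  structure(list(homography = homography,
                 occlusion_regions = occlusion_regions,
                 object_jitter_cm = object_jitter_cm,
                 object_jitter_deg = object_jitter_deg),
            class = "camera_params")
}

#' A mild oblique-view homography
#'
#' The rectifying transform of a camera looking at the arena at a slight
#' angle: the arena corners image to a trapezoid. Used as the default
#' perspective distortion of the synthetic generator.
#'
#' @param arena [arena_spec()].
#' @param tilt Fractional keystone of the far edge (default 0.08).
#' @return A `homography` mapping camera coordinates to arena coordinates.
#' @export
tilted_view_homography <- function(arena = arena_spec(), tilt = 0.08) {
  L <- arena$length_cm
  W <- arena$width_cm
  # camera-plane corner images of (0,0), (L,0), (L,W), (0,W)
  cam <- rbind(c(0, 0),
               c(L, 0),
               c(L * (1 - tilt), W * (1 - tilt / 2)),
               c(L * tilt, W * (1 - tilt / 2)))
  fit_homography(cam, arena_corners(arena))
}

#' Degrade a ground-truth trial through the synthetic camera
#'
#' Pushes positions through the inverse rectifying homography (perspective
#' distortion), deletes observations inside `"missing"` occlusion regions,
#' and blanks coordinates of observations over the object while keeping an
#' at-object record. Emits exactly the corner correspondences that
#' [fit_homography()] needs to undo the distortion.
#'
#' @param traj Ground-truth [trajectory()] in the arena frame.
#' @param cam [camera_params()].
#' @param arena [arena_spec()].
#' @return A list: `trajectory` (camera-frame detections; at-object rows have
#'   `NA` coordinates, `valid = FALSE`, `at_object = TRUE`), `corners`
#'   (tibble `source_x`, `source_y`, `target_x`, `target_y`), `occluded`
#'   (per-label deletion counts).
#' @export
apply_camera <- function(traj, cam = camera_params(), arena = arena_spec()) {
  stopifnot(inherits(traj, "shoal_traj"), inherits(cam, "camera_params"))
  Hinv <- invert_homography(cam$homography)
  out <- traj
  if (!"at_object" %in% names(out)) out$at_object <- FALSE
  drop <- rep(FALSE, nrow(out))
  counts <- tibble::tibble(label = character(), n = integer())
  for (mr in cam$occlusion_regions) {
    inside <- in_region(out$x, out$y, mr$region) & !drop & !out$at_object
    if (mr$policy == "missing") {
      drop <- drop | inside
    } else {
      out$at_object[inside] <- TRUE
    }
    counts <- dplyr::bind_rows(counts, tibble::tibble(label = mr$label, n = sum(inside)))
  }
  out <- out[!drop, , drop = FALSE]
  campts <- apply_homography(cbind(out$x, out$y), Hinv)
  out$x <- ifelse(out$at_object, NA_real_, campts$x)
  out$y <- ifelse(out$at_object, NA_real_, campts$y)
  out$valid <- out$valid & !out$at_object & campts$valid
  tgt <- arena_corners(arena)
  src <- apply_homography(tgt, Hinv)
  list(
    trajectory = new_trajectory(out, fps = traj_fps(traj), duration_s = traj_duration(traj)),
    corners = tibble::tibble(source_x = src$x, source_y = src$y,
                             target_x = tgt[, 1], target_y = tgt[, 2]),
    occluded = counts
  )
}

default_group_params <- function(brain_size, sex = "female", shoal_size = 4) {
  # qualitative presets: large-brained females inspect less and hold a wider,
  # shoal-size-dependent ring; everyone else shares the baseline
  rate <- if (shoal_size >= 4) 32 else 23
  if (sex == "female" && brain_size == "large") {
    behaviour_params(inspection_rate_per_hour = rate / 2,
                     avoidance_radius_cm = 10 + 2 * (shoal_size < 4))
  } else {
    behaviour_params(inspection_rate_per_hour = rate)
  }
}

#' Simulate a complete synthetic study
#'
#' Generates every trial of a crossed design (one trial per group), with
#' per-trial stimulus-pose jitter, deterministic per-trial seeds derived from
#' `base_seed`, and a ground-truth record of all generating parameters.
#' When `out_dir` is given, each trial's trajectory and event log are written
#' as CSV with a YAML manifest (the formats read by [read_trial()]), so the
#' generator doubles as a fixture factory; otherwise everything is returned
#' in memory. Identical `base_seed` gives identical output, file-for-file.
#'
#' @param design Tibble of trial-level factors; must contain `replicate` and
#'   any columns used by `params_fn`. One row per group (trial).
#' @param params_fn Function `(design_row) -> behaviour_params()` giving each
#'   cell's generating parameters; defaults to qualitative presets keyed by
#'   `brain_size`/`sex`/`shoal_size` columns.
#' @param arena [arena_spec()].
#' @param reference [object_pose()] around which trial poses are jittered.
#' @param cam [camera_params()]; its jitter fields set the pose jitter.
#' @param duration_s,fps Trial length (s) and frame rate.
#' @param base_seed Integer master seed.
#' @param out_dir Optional directory to write trial files into.
#' @return A list of trials; each has `trajectory`, `events`, `pose`,
#'   `params`, `info` (the design row), `seed`, and (if written) `paths`.
#' @export
simulate_study <- function(design, params_fn = NULL, arena = arena_spec(),
                           reference = NULL, cam = camera_params(),
                           duration_s = 1200, fps = 30, base_seed = 1,
                           out_dir = NULL) {
  design <- tibble::as_tibble(design)
  stopifnot(nrow(design) >= 1)
  if (is.null(reference)) reference <- object_pose(12, arena$width_cm / 2, 90)
  if (is.null(params_fn)) {
    params_fn <- function(row) {
      default_group_params(
        brain_size = if ("brain_size" %in% names(row)) row$brain_size else "small",
        sex = if ("sex" %in% names(row)) row$sex else "female",
        shoal_size = if ("shoal_size" %in% names(row)) row$shoal_size else 4
      )
    }
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, , drop = FALSE]
    seed_i <- (as.integer(base_seed) * 1009L + i * 7919L) %% 2000000011L
    params <- params_fn(row)
    if (is.null(params)) {
      abort(sprintf("no behaviour parameters for design row %d", i),
            class = "shoalwatch_validation")
    }
    pose <- withr::with_seed(seed_i, jitter_pose(reference, cam, arena))
    shoal <- if ("shoal_size" %in% names(row)) row$shoal_size else 4
    tr <- simulate_trial(params, arena, pose, shoal_size = shoal,
                         duration_s = duration_s, fps = fps, seed = seed_i + 1L)
    tr$info <- row
    tr$seed <- seed_i
    if (!is.null(out_dir)) {
      tr$paths <- write_trial(tr, file.path(out_dir, sprintf("trial_%03d", i)),
                              arena = arena, fps = fps, duration_s = duration_s)
    }
    trials[[i]] <- tr
  }
  trials
}

jitter_pose <- function(reference, cam, arena) {
  x <- reference$x_cm + rnorm(1, 0, cam$object_jitter_cm)
  y <- reference$y_cm + rnorm(1, 0, cam$object_jitter_cm)
  x <- min(max(x, 2), arena$length_cm - 2)
  y <- min(max(y, 2), arena$width_cm - 2)
  h <- if (is.na(reference$heading_deg)) NA_real_ else {
    (reference$heading_deg + rnorm(1, 0, cam$object_jitter_deg)) %% 360
  }
  fp <- reference$footprint
  if (!is.null(fp) && fp$type == "capsule") {
    fp <- region_capsule(x, y, ifelse(is.na(h), 0, h), fp$length_cm, fp$width_cm)
  }
  object_pose(x, y, h, kind = reference$kind, footprint = fp)
}
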