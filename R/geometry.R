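#' Fit a projective (homography) transform from point correspondences
#'
#' Estimates the 3 x 3 planar projective transform mapping source points onto
#' target points, as used to rectify obliquely filmed tank coordinates onto
#' the rectangular arena plane. Four correspondences give the exact direct
#' linear solution; five or more are solved in least squares. Coordinates are
#' Hartley-normalised before the DLT for numerical conditioning, and the
#' returned matrix is scaled so its bottom-right coefficient is 1.
#'
#' @param source,target n x 2 matrices (or data frames with columns x, y) of
#'   corresponding points, n >= 4, no three source points collinear.
#' @return A 3 x 3 matrix of class `homography` (column-vector convention:
#'   the transform acts as `H %*% c(x, y, 1)`).
#' @export
#' @examples
#' h <- fit_homography(arena_corners(), arena_corners() + 3)
#' apply_homography(cbind(0, 0), h) # translated by (3, 3)
fit_homography <- function(source, target) {
  src <- as_xy_matrix(source)
  dst <- as_xy_matrix(target)
  n <- nrow(src)
  if (n < 4 || nrow(dst) != n) {
    abort("need at least 4 point correspondences", class = "shoalwatch_geometry_error")
  }
  if (any_three_collinear(src)) {
    abort("degenerate configuration: three or more source points are collinear",
          class = "shoalwatch_geometry_error")
  }
  Ts <- hartley_norm(src)
  Td <- hartley_norm(dst)
  sn <- transform_rows(src, Ts)
  dn <- transform_rows(dst, Td)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    xs <- sn[i, 1]; ys <- sn[i, 2]
    xd <- dn[i, 1]; yd <- dn[i, 2]
    A[2 * i - 1, ] <- c(-xs, -ys, -1, 0, 0, 0, xd * xs, xd * ys, xd)
    A[2 * i, ]     <- c(0, 0, 0, -xs, -ys, -1, yd * xs, yd * ys, yd)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] / sv$d[1] < 1e-13) {
    abort("degenerate configuration: correspondences do not determine a homography",
          class = "shoalwatch_geometry_error")
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(H[3, 3]) < 1e-12 * max(abs(H))) {
    abort("homography cannot be normalised to bottom-right coefficient 1",
          class = "shoalwatch_geometry_error")
  }
  H <- H / H[3, 3]
  structure(H, class = c("homography", "matrix", "array"))
}

as_xy_matrix <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p[, c("x", "y")])
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  stopifnot(ncol(p) == 2)
  unname(p)
}

any_three_collinear <- function(p) {
  n <- nrow(p)
  if (n > 8) return(FALSE) # only guard small exact configurations
  idx <- utils::combn(n, 3)
  scale2 <- max(1, max(abs(p))^2)
  for (k in seq_len(ncol(idx))) {
    a <- p[idx[1, k], ]; b <- p[idx[2, k], ]; c <- p[idx[3, k], ]
    area2 <- abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    if (area2 < 1e-10 * scale2) return(TRUE)
  }
  FALSE
}

hartley_norm <- function(p) {
  ctr <- colMeans(p)
  d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  s <- if (mean(d) > 1e-12) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

transform_rows <- function(p, H) {
  q <- cbind(p, 1) %*% t(H)
  q[, 1:2] / q[, 3]
}

#' Apply a homography to points
#'
#' Maps 2-D points through a projective transform with homogeneous
#' normalisation. Points sent (numerically) to the line at infinity are
#' returned as `NA` and flagged invalid rather than raising an error. The
#' composition convention is `apply_homography(p, B %*% A)` ==
#' `apply_homography(apply_homography(p, A), B)`.
#'
#' @param points n x 2 matrix or data frame with columns x, y.
#' @param h A `homography` (any 3 x 3 matrix is accepted).
#' @return A tibble with columns `x`, `y`, `valid`.
#' @export
apply_homography <- function(points, h) {
  p <- as_xy_matrix(points)
  h <- unclass(h)
  stopifnot(is.matrix(h), all(dim(h) == c(3, 3)))
  q <- cbind(p, 1) %*% t(h)
  w <- q[, 3]
  ok <- is.finite(w) & abs(w) > 1e-12
  x <- ifelse(ok, q[, 1] / w, NA_real_)
  y <- ifelse(ok, q[, 2] / w, NA_real_)
  tibble::tibble(x = x, y = y, valid = ok)
}

#' Invert a homography
#'
#' @param h A `homography`.
#' @return The inverse transform, renormalised to bottom-right coefficient 1.
#' @export
invert_homography <- function(h) {
  Hi <- solve(unclass(h))
  Hi <- Hi / Hi[3, 3]
  structure(Hi, class = c("homography", "matrix", "array"))
}

#' Rectify a trajectory into the arena frame
#'
#' Pushes every detection through the camera-to-arena homography. Detections
#' mapped to the plane at infinity are marked invalid.
#'
#' @param traj A [trajectory()].
#' @param h The camera-to-arena `homography` (from [fit_homography()] on the
#'   trial's corner correspondences).
#' @return The rectified trajectory.
#' @export
rectify_trajectory <- function(traj, h) {
  stopifnot(inherits(traj, "shoal_traj"))
  out <- apply_homography(cbind(traj$x, traj$y), h)
  traj$x <- out$x
  traj$y <- out$y
  traj$valid <- traj$valid & out$valid
  traj
}

#' Rigid transform taking one object pose onto another
#'
#' The translation + rotation that moves the observed stimulus pose onto the
#' reference pose; applied to a whole trajectory it overlays the objects of
#' different trials. If either heading is `NA` the rotation component is
#' skipped (translation-only overlay) with a warning.
#'
#' @param observed,reference [object_pose()] objects.
#' @return A 3 x 3 `homography` encoding the rigid motion.
#' @export
rigid_from_poses <- function(observed, reference) {
  stopifnot(inherits(observed, "object_pose"), inherits(reference, "object_pose"))
  if (is.na(observed$heading_deg) || is.na(reference$heading_deg)) {
    warn("object heading unavailable: rotation skipped, translation-only overlay")
    ang <- 0
  } else {
    ang <- (reference$heading_deg - observed$heading_deg) * pi / 180
  }
  R <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2, byrow = TRUE)
  t <- c(reference$x_cm, reference$y_cm) - R %*% c(observed$x_cm, observed$y_cm)
  H <- rbind(cbind(R, t), c(0, 0, 1))
  structure(H, class = c("homography", "matrix", "array"))
}

#' Align a rectified trajectory onto a reference object pose
#'
#' Applies the rigid motion from [rigid_from_poses()] to every observation so
#' that stimulus objects from all trials coincide. Distances between
#' simultaneous points are preserved exactly (rigid motion). Points that leave
#' the nominal arena after alignment are retained and flagged in an
#' `in_arena` column; they stay valid but fall outside every grid cell.
#'
#' @param traj Rectified [trajectory()].
#' @param observed The trial's measured object pose.
#' @param reference The common reference pose (see [reference_pose()]).
#' @param arena [arena_spec()] used for the `in_arena` flag.
#' @return The aligned trajectory with an `in_arena` column.
#' @export
align_trajectory <- function(traj, observed, reference, arena = arena_spec()) {
  stopifnot(inherits(traj, "shoal_traj"))
  H <- rigid_from_poses(observed, reference)
  q <- cbind(traj$x, traj$y, 1) %*% t(unclass(H))
  traj$x <- q[, 1]
  traj$y <- q[, 2]
  traj$in_arena <- !is.na(traj$x) & !is.na(traj$y) &
    traj$x >= 0 & traj$x <= arena$length_cm &
    traj$y >= 0 & traj$y <= arena$width_cm
  traj
}

#' Component-wise mean reference pose
#'
#' The common overlay target: the mean centroid and circular-mean heading over
#' all observed trial poses. Minimises average displacement of the overlays;
#' any fixed pose can be supplied instead wherever a reference pose is taken.
#'
#' @param poses List of [object_pose()] objects.
#' @return An [object_pose()].
#' @export
reference_pose <- function(poses) {
  stopifnot(length(poses) >= 1)
  xs <- vapply(poses, function(p) p$x_cm, numeric(1))
  ys <- vapply(poses, function(p) p$y_cm, numeric(1))
  hs <- vapply(poses, function(p) p$heading_deg, numeric(1))
  heading <- if (anyNA(hs)) NA_real_ else {
    th <- hs * pi / 180
    (atan2(mean(sin(th)), mean(cos(th))) * 180 / pi) %% 360
  }
  p1 <- poses[[1]]
  fp <- p1$footprint
  if (!is.null(fp) && fp$type == "capsule") {
    fp <- region_capsule(mean(xs), mean(ys), ifelse(is.na(heading), 0, heading),
                         fp$length_cm, fp$width_cm)
  }
  object_pose(mean(xs), mean(ys), heading, kind = p1$kind, footprint = fp)
}

#' Apply the study's missing-data policy to a trajectory
#'
#' Observations inside a region with policy `"missing"` have their validity
#' flag cleared; observations inside a `"lowest_bin_for_distance"` region gain
#' an `at_object` flag consumed by the distance profiles (such observations
#' enter the lowest distance bin, mirroring fish swimming over the stimulus).
#' Masking is idempotent. Per-label masked counts are attached as the
#' `mask_counts` attribute.
#'
#' @param traj Aligned [trajectory()].
#' @param regions List of [mask_region()] definitions (may be empty).
#' @return The masked trajectory.
#' @export
mask_trajectory <- function(traj, regions = list()) {
  stopifnot(inherits(traj, "shoal_traj"))
  if (!"at_object" %in% names(traj)) traj$at_object <- FALSE
  counts <- tibble::tibble(label = character(), policy = character(), n = integer())
  for (mr in regions) {
    stopifnot(inherits(mr, "mask_region"))
    inside <- !is.na(traj$x) & !is.na(traj$y) & in_region(traj$x, traj$y, mr$region)
    if (mr$policy == "missing") {
      hit <- inside & traj$valid
      traj$valid[hit] <- FALSE
    } else {
      hit <- inside & !traj$at_object
      traj$at_object[hit] <- TRUE
    }
    counts <- dplyr::bind_rows(counts,
      tibble::tibble(label = mr$label, policy = mr$policy, n = sum(hit)))
  }
  attr(traj, "mask_counts") <- counts
  traj
}
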