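#' Arena specification
#'
#' Describes the rectangular experimental tank footprint seen from above.
#' The default is a 59 x 29 cm arena analysed on a 0.5 cm occupancy grid.
#' The arena frame has its origin at the corner nearest the stimulus end,
#' x running along the long (59 cm) axis and y along the short (29 cm)
#' axis; coordinates are continuous and in centimetres.
#'
#' @param length_cm Long-axis extent in cm.
#' @param width_cm Short-axis extent in cm.
#' @param grid_cell_cm Side of a square occupancy grid cell in cm. Both
#'   arena extents must be integer multiples of this value so that the
#'   grid tiles the arena exactly.
#'
#' @return An object of class `arena_spec`.
#' @export
#' @examples
#' arena_spec()
arena_spec <- function(length_cm = 59, width_cm = 29, grid_cell_cm = 0.5) {
  if (!all(is.finite(c(length_cm, width_cm, grid_cell_cm))) ||
      length_cm <= 0 || width_cm <= 0 || grid_cell_cm <= 0) {
    abort("arena dimensions and grid cell must be strictly positive", class = "shoalwatch_error")
  }
  mult <- c(length_cm, width_cm) / grid_cell_cm
  if (any(abs(mult - round(mult)) > 1e-9)) {
    abort("arena extents must be integer multiples of the grid cell size", class = "shoalwatch_error")
  }
  structure(
    list(length_cm = length_cm, width_cm = width_cm, grid_cell_cm = grid_cell_cm),
    class = "arena_spec"
  )
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %g x %g cm, %g cm grid\n",
              x$length_cm, x$width_cm, x$grid_cell_cm))
  invisible(x)
}

#' Arena corner coordinates
#'
#' Corners in arena-frame cm, in the fixed order (0,0), (L,0), (L,W), (0,W).
#' This order is also the convention used for camera-corner correspondences.
#'
#' @param arena An [arena_spec()].
#' @return A 4 x 2 numeric matrix with columns x, y.
#' @export
arena_corners <- function(arena = arena_spec()) {
  L <- arena$length_cm
  W <- arena$width_cm
  matrix(c(0, 0, L, 0, L, W, 0, W), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("x", "y")))
}

# ---- planar regions ---------------------------------------------------------

#' Planar regions in the arena frame
#'
#' Simple region primitives used for stimulus-object footprints and masking:
#' axis-aligned rectangles, circles, and capsules (a line segment dilated by a
#' radius; the usual footprint of an elongated predator model).
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in cm.
#' @param cx,cy Centre coordinates in cm.
#' @param radius Circle radius in cm.
#' @param heading_deg Orientation of the capsule long axis, degrees
#'   anticlockwise from the +x axis.
#' @param length_cm Total capsule length (tip to tip) in cm.
#' @param width_cm Capsule width (2 x dilation radius) in cm.
#' @return A `region` object.
#' @name regions
NULL

#' @rdname regions
#' @export
region_rect <- function(xmin, xmax, ymin, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  structure(list(type = "rect", xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "region")
}

#' @rdname regions
#' @export
region_circle <- function(cx, cy, radius) {
  stopifnot(radius > 0)
  structure(list(type = "circle", cx = cx, cy = cy, radius = radius),
            class = "region")
}

#' @rdname regions
#' @export
region_capsule <- function(cx, cy, heading_deg, length_cm, width_cm) {
  stopifnot(length_cm >= width_cm, width_cm > 0)
  structure(list(type = "capsule", cx = cx, cy = cy, heading_deg = heading_deg,
                 length_cm = length_cm, width_cm = width_cm),
            class = "region")
}

capsule_segment <- function(region) {
  a <- (region$length_cm - region$width_cm) / 2 # half segment length
  th <- region$heading_deg * pi / 180
  u <- c(cos(th), sin(th))
  list(p1 = c(region$cx, region$cy) - a * u,
       p2 = c(region$cx, region$cy) + a * u,
       radius = region$width_cm / 2)
}

dist_point_segment <- function(x, y, p1, p2) {
  vx <- p2[1] - p1[1]
  vy <- p2[2] - p1[2]
  len2 <- vx^2 + vy^2
  if (len2 < 1e-300) return(sqrt((x - p1[1])^2 + (y - p1[2])^2))
  t <- pmin(pmax(((x - p1[1]) * vx + (y - p1[2]) * vy) / len2, 0), 1)
  sqrt((x - p1[1] - t * vx)^2 + (y - p1[2] - t * vy)^2)
}

#' Test points against a region
#'
#' @param x,y Numeric vectors of coordinates (cm, arena frame).
#' @param region A [regions] object.
#' @return Logical vector, `TRUE` where the point lies inside (boundary
#'   included).
#' @export
in_region <- function(x, y, region) {
  stopifnot(inherits(region, "region"))
  switch(region$type,
    rect = x >= region$xmin & x <= region$xmax & y >= region$ymin & y <= region$ymax,
    circle = (x - region$cx)^2 + (y - region$cy)^2 <= region$radius^2,
    capsule = {
      seg <- capsule_segment(region)
      dist_point_segment(x, y, seg$p1, seg$p2) <= seg$radius
    },
    abort(paste0("unknown region type: ", region$type), class = "shoalwatch_error")
  )
}

#' Distance from points to a region boundary (outside only)
#'
#' Euclidean distance to the nearest point of the region; 0 for points inside.
#'
#' @inheritParams in_region
#' @return Numeric vector of non-negative distances (cm).
#' @export
region_distance <- function(x, y, region) {
  stopifnot(inherits(region, "region"))
  switch(region$type,
    rect = {
      dx <- pmax(region$xmin - x, 0, x - region$xmax)
      dy <- pmax(region$ymin - y, 0, y - region$ymax)
      sqrt(dx^2 + dy^2)
    },
    circle = pmax(sqrt((x - region$cx)^2 + (y - region$cy)^2) - region$radius, 0),
    capsule = {
      seg <- capsule_segment(region)
      pmax(dist_point_segment(x, y, seg$p1, seg$p2) - seg$radius, 0)
    },
    abort(paste0("unknown region type: ", region$type), class = "shoalwatch_error")
  )
}

# ---- stimulus object pose ---------------------------------------------------

#' Stimulus object pose
#'
#' Position, orientation and footprint of the stimulus item (predator model or
#' novel-object control) in the arena frame. The heading is the direction the
#' object's head points (degrees anticlockwise from +x); for a symmetric novel
#' object it is a nominal long-axis orientation.
#'
#' @param x_cm,y_cm Centroid, arena-frame cm.
#' @param heading_deg Orientation in degrees; `NA` when unknown (rigid
#'   alignment then skips the rotation component, with a warning).
#' @param kind `"predator_model"` or `"novel_object"`.
#' @param footprint A [regions] object occupied by the item, `NULL` for a
#'   point-like object, or `"capsule"` (default) for a 12 x 3 cm capsule at
#'   the pose (the size of the fishing-lure models used in this kind of
#'   assay).
#' @param arena Optional [arena_spec()]; if supplied, the centroid is checked
#'   to lie inside the arena.
#' @return An object of class `object_pose`.
#' @export
object_pose <- function(x_cm, y_cm, heading_deg = 90, kind = c("predator_model", "novel_object"),
                        footprint = "capsule", arena = NULL) {
  kind <- match.arg(kind)
  if (identical(footprint, "capsule")) {
    footprint <- region_capsule(x_cm, y_cm, ifelse(is.na(heading_deg), 0, heading_deg),
                                length_cm = 12, width_cm = 3)
  }
  if (!is.null(footprint)) stopifnot(inherits(footprint, "region"))
  if (!is.null(arena)) {
    if (x_cm < 0 || x_cm > arena$length_cm || y_cm < 0 || y_cm > arena$width_cm) {
      abort("object centroid outside arena", class = "shoalwatch_error")
    }
  }
  structure(list(x_cm = x_cm, y_cm = y_cm, heading_deg = heading_deg,
                 kind = kind, footprint = footprint),
            class = "object_pose")
}

#' @export
print.object_pose <- function(x, ...) {
  cat(sprintf("<object_pose> %s at (%.2f, %.2f) cm, heading %s deg\n",
              x$kind, x$x_cm, x$y_cm,
              ifelse(is.na(x$heading_deg), "NA", format(x$heading_deg))))
  invisible(x)
}

#' Mask-region definition
#'
#' A region of the arena where tracked positions are unreliable, together with
#' the policy applied there: `"missing"` clears the validity flag (the
#' observation is dropped from occupancy analysis), while
#' `"lowest_bin_for_distance"` keeps a dedicated at-object flag so the
#' observation still enters distance profiles in the lowest distance bin.
#'
#' @param region A [regions] object.
#' @param label One of `"ledge"`, `"over_object"`, `"other"`.
#' @param policy `"missing"` or `"lowest_bin_for_distance"`.
#' @return An object of class `mask_region`.
#' @export
mask_region <- function(region, label = c("ledge", "over_object", "other"),
                        policy = c("missing", "lowest_bin_for_distance")) {
  stopifnot(inherits(region, "region"))
  structure(list(region = region, label = match.arg(label), policy = match.arg(policy)),
            class = "mask_region")
}

# ---- trajectories -----------------------------------------------------------

#' Construct a trajectory table
#'
#' A trajectory is a tibble of per-frame detections of unidentified
#' individuals with columns `frame` (0-based integer), `point_id` (arbitrary
#' within-frame identifier), `x`, `y` (cm) and `valid` (logical). Frame rate
#' and trial duration travel along as attributes.
#'
#' @param df Data frame with at least `frame`, `x`, `y`; `point_id` defaults
#'   to 1 and `valid` to `TRUE`.
#' @param fps Frames per second (default 30).
#' @param duration_s Trial duration in seconds (default 1200, i.e. 20 min).
#' @return A tibble of class `shoal_traj`.
#' @export
trajectory <- function(df, fps = 30, duration_s = 1200) {
  stopifnot(all(c("frame", "x", "y") %in% names(df)))
  df <- tibble::as_tibble(df)
  if (!"point_id" %in% names(df)) df$point_id <- 1L
  if (!"valid" %in% names(df)) df$valid <- TRUE
  if (nrow(df) > 0 && (min(df$frame) < 0 || max(df$frame) >= round(fps * duration_s))) {
    abort("frame indices must lie in [0, fps * duration_s)", class = "shoalwatch_error")
  }
  df <- df[, unique(c("frame", "point_id", "x", "y", "valid",
                      intersect(names(df), c("at_object", "in_arena")))), drop = FALSE]
  new_trajectory(df, fps = fps, duration_s = duration_s)
}

new_trajectory <- function(df, fps, duration_s) {
  df <- tibble::as_tibble(df)
  attr(df, "fps") <- fps
  attr(df, "duration_s") <- duration_s
  class(df) <- unique(c("shoal_traj", class(df)))
  df
}

#' @rdname trajectory
#' @param traj A `shoal_traj` trajectory.
#' @export
traj_fps <- function(traj) attr(traj, "fps")

#' @rdname trajectory
#' @export
traj_duration <- function(traj) attr(traj, "duration_s")
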