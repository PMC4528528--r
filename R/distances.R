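#' Distance-bin specification
#'
#' Half-open bins `[k*w, (k+1)*w)` tiling `[0, max_distance_cm]`; anything at
#' or beyond the upper edge falls into the last bin. Observations flagged
#' at-object are forced into the lowest bin.
#'
#' @param bin_width_cm Bin width in cm (default 1).
#' @param max_distance_cm Upper range; defaults to the arena diagonal.
#' @param arena [arena_spec()] used for the default maximum.
#' @return An object of class `distance_bins`.
#' @export
distance_bins <- function(bin_width_cm = 1, max_distance_cm = NULL,
                          arena = arena_spec()) {
  if (!is.finite(bin_width_cm) || bin_width_cm <= 0) {
    abort("bin width must be positive", class = "shoalwatch_error")
  }
  if (is.null(max_distance_cm)) {
    max_distance_cm <- sqrt(arena$length_cm^2 + arena$width_cm^2)
  }
  n_bins <- as.integer(ceiling(max_distance_cm / bin_width_cm - 1e-9))
  structure(list(bin_width_cm = bin_width_cm,
                 max_distance_cm = max_distance_cm,
                 n_bins = n_bins,
                 centres = (seq_len(n_bins) - 0.5) * bin_width_cm),
            class = "distance_bins")
}

#' Distance of every observation to the stimulus object
#'
#' Euclidean distance from each usable observation to the object reference
#' point (the centroid by default; optionally the nearest footprint point).
#' Observations carrying the at-object flag report distance 0 even when their
#' coordinates are unknown (they enter the lowest bin); observations masked
#' as missing and not at-object emit nothing.
#'
#' @param traj An aligned, masked [trajectory()].
#' @param pose The reference [object_pose()].
#' @param reference `"centroid"` (default) or `"footprint"`.
#' @return A tibble `frame`, `point_id`, `distance`, `at_object`.
#' @export
distance_series <- function(traj, pose, reference = c("centroid", "footprint")) {
  stopifnot(inherits(traj, "shoal_traj"), inherits(pose, "object_pose"))
  reference <- match.arg(reference)
  at_obj <- if ("at_object" %in% names(traj)) traj$at_object else rep(FALSE, nrow(traj))
  keep <- traj$valid | at_obj
  sub <- traj[keep, , drop = FALSE]
  at_obj <- at_obj[keep]
  d <- if (reference == "centroid") {
    sqrt((sub$x - pose$x_cm)^2 + (sub$y - pose$y_cm)^2)
  } else {
    region_distance(sub$x, sub$y, pose$footprint)
  }
  d[at_obj] <- 0
  tibble::tibble(frame = sub$frame, point_id = sub$point_id,
                 distance = d, at_object = at_obj)
}

#' Histogram density of distances
#'
#' @param distances Numeric vector of distances (cm), or the tibble returned
#'   by [distance_series()].
#' @param bins A [distance_bins()].
#' @return A tibble `bin_lo`, `bin_hi`, `bin_centre`, `density`; densities
#'   are bin fractions summing to 1.
#' @export
distance_density <- function(distances, bins = distance_bins()) {
  if (is.data.frame(distances)) distances <- distances$distance
  distances <- distances[is.finite(distances)]
  if (length(distances) == 0) {
    abort("no distances to bin", class = "shoalwatch_empty_trial")
  }
  w <- bins$bin_width_cm
  idx <- pmin(pmax(floor(distances / w), 0), bins$n_bins - 1) + 1L
  counts <- tabulate(idx, nbins = bins$n_bins)
  tibble::tibble(bin_lo = (seq_len(bins$n_bins) - 1) * w,
                 bin_hi = seq_len(bins$n_bins) * w,
                 bin_centre = bins$centres,
                 density = counts / length(distances))
}

#' Monte Carlo uniform-arena distance null
#'
#' The distance-to-object density expected when positions are drawn uniformly
#' over the arena footprint. By default the object footprint is excluded from
#' the support (fish cannot occupy the object's area); pass
#' `exclude_object = FALSE` for the pure-rectangle support. A non-rectangular
#' support region (e.g. a disc, for validating against the closed-form
#' annulus density) can be supplied via `support`.
#'
#' @param arena [arena_spec()] giving the rectangular footprint (ignored when
#'   `support` is given).
#' @param pose [object_pose()]; distances are taken to its centroid.
#' @param bins [distance_bins()].
#' @param n_samples Number of uniform draws (>= 1e5 recommended).
#' @param exclude_object Drop draws inside the object footprint?
#' @param support Optional [regions] object to sample uniformly instead of
#'   the arena rectangle.
#' @param seed Optional integer; same seed gives bit-identical output.
#' @return A density tibble as from [distance_density()].
#' @export
uniform_null_density <- function(arena = arena_spec(), pose, bins = distance_bins(),
                                 n_samples = 1e6, exclude_object = TRUE,
                                 support = NULL, seed = NULL) {
  stopifnot(inherits(pose, "object_pose"), n_samples >= 1)
  draw <- function() {
    if (is.null(support)) {
      x <- runif(n_samples, 0, arena$length_cm)
      y <- runif(n_samples, 0, arena$width_cm)
    } else {
      bb <- region_bbox(support)
      x <- numeric(0); y <- numeric(0)
      while (length(x) < n_samples) {
        need <- n_samples - length(x)
        cx <- runif(ceiling(need * 1.6) + 16, bb[1], bb[2])
        cy <- runif(length(cx), bb[3], bb[4])
        keep <- in_region(cx, cy, support)
        x <- c(x, cx[keep]); y <- c(y, cy[keep])
      }
      x <- x[seq_len(n_samples)]; y <- y[seq_len(n_samples)]
    }
    if (exclude_object && !is.null(pose$footprint)) {
      keep <- !in_region(x, y, pose$footprint)
      x <- x[keep]; y <- y[keep]
    }
    sqrt((x - pose$x_cm)^2 + (y - pose$y_cm)^2)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- distance_density(d, bins)
  attr(out, "n_samples") <- length(d)
  out
}

region_bbox <- function(region) {
  switch(region$type,
    rect = c(region$xmin, region$xmax, region$ymin, region$ymax),
    circle = c(region$cx - region$radius, region$cx + region$radius,
               region$cy - region$radius, region$cy + region$radius),
    capsule = {
      h <- region$length_cm / 2
      c(region$cx - h, region$cx + h, region$cy - h, region$cy + h)
    })
}

#' Relative distance profile with bootstrap confidence band
#'
#' Subtracts the uniform-arena null from each trial's distance density (so a
#' flat-zero curve means "no different from random placement"), takes the
#' element-wise median across trials as the group curve, and attaches a
#' percentile-bootstrap 95% band obtained by resampling trials (the sampling
#' unit) with replacement.
#'
#' @param per_trial Long tibble `trial`, `bin_centre`, `density` (or a named
#'   list of [distance_density()] tibbles) for >= 2 trials on one bin spec.
#' @param null Null density tibble from [uniform_null_density()], or `NULL`
#'   for an absolute (non-relative) profile.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Band coverage (default 0.95).
#' @param seed Optional integer seed for the bootstrap.
#' @return A tibble of class `distance_profile`: `bin_centre`, `median`,
#'   `ci_low`, `ci_high`; per-trial relative curves in the `per_trial`
#'   attribute, `relative` flag attribute.
#' @export
relative_distance_profile <- function(per_trial, null = NULL, n_boot = 1000,
                                      conf = 0.95, seed = NULL) {
  if (!is.data.frame(per_trial)) {
    stopifnot(is.list(per_trial))
    if (is.null(names(per_trial))) names(per_trial) <- paste0("trial_", seq_along(per_trial))
    per_trial <- dplyr::bind_rows(lapply(per_trial, tibble::as_tibble), .id = "trial")
  }
  stopifnot(all(c("trial", "bin_centre", "density") %in% names(per_trial)))
  per_trial <- dplyr::arrange(per_trial, .data$trial, .data$bin_centre)
  trials <- unique(per_trial$trial)
  if (length(trials) < 2) {
    abort("relative profiles need at least 2 trials", class = "shoalwatch_sample_size")
  }
  centres <- unique(per_trial$bin_centre)
  M <- matrix(per_trial$density, nrow = length(trials), byrow = TRUE)
  if (!is.null(null)) {
    stopifnot(nrow(null) == length(centres))
    M <- sweep(M, 2, null$density)
  }
  med <- apply(M, 2, median)
  boot <- function() {
    idx <- matrix(sample.int(length(trials), length(trials) * n_boot, replace = TRUE),
                  nrow = n_boot)
    t(apply(idx, 1, function(i) apply(M[i, , drop = FALSE], 2, median)))
  }
  B <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  a <- (1 - conf) / 2
  ci <- apply(B, 2, quantile, probs = c(a, 1 - a), names = FALSE)
  out <- tibble::tibble(bin_centre = centres, median = med,
                        ci_low = ci[1, ], ci_high = ci[2, ])
  attr(out, "per_trial") <- M
  attr(out, "trials") <- trials
  attr(out, "relative") <- !is.null(null)
  attr(out, "n_boot") <- n_boot
  class(out) <- unique(c("distance_profile", class(out)))
  out
}

#' Peak of a distance profile
#'
#' Bin centre at the global maximum of the median curve; the usual summary of
#' where a group concentrates relative to random placement.
#'
#' @param profile A `distance_profile`.
#' @return Bin-centre distance in cm.
#' @export
profile_peak <- function(profile) {
  stopifnot(inherits(profile, "distance_profile"))
  profile$bin_centre[which.max(profile$median)]
}
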