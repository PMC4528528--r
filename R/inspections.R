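#' Summarise scored inspection events for one trial
#'
#' Turns the manually scored event log (start, end, inspecting-group size)
#' into the per-trial behavioural responses: number of inspections, mean
#' inspection duration, total inspection time per fish, an occurrence flag,
#' and the hourly rate. Time per fish is person-time by default — each
#' event contributes duration x group size, and the total is divided by the
#' shoal size; `"union_time"` instead measures the time during which at
#' least one fish was inspecting. Overlapping events are allowed and are not
#' merged (two subgroups can inspect simultaneously).
#'
#' @param events Data frame with columns `start_s`, `end_s`, `group_size`
#'   (may have zero rows).
#' @param shoal_size Number of fish in the trial's shoal.
#' @param duration_s Trial duration in seconds (default 1200).
#' @param time_per_fish `"person_time"` (default) or `"union_time"`.
#' @return A one-row tibble: `n_inspections`, `mean_duration_s`,
#'   `time_per_fish_s`, `occurred`, `rate_per_hour`.
#' @export
#' @examples
#' ev <- tibble::tibble(start_s = 10, end_s = 20, group_size = 2)
#' summarize_inspections(ev, shoal_size = 4)
summarize_inspections <- function(events, shoal_size, duration_s = 1200,
                                  time_per_fish = c("person_time", "union_time")) {
  time_per_fish <- match.arg(time_per_fish)
  stopifnot(shoal_size >= 1, duration_s > 0)
  events <- tibble::as_tibble(events)
  n <- nrow(events)
  if (n > 0) {
    stopifnot(all(c("start_s", "end_s", "group_size") %in% names(events)))
    bad <- events$start_s < 0 | events$start_s >= events$end_s |
      events$end_s > duration_s + 1e-9 | events$group_size < 1 |
      events$group_size > shoal_size
    if (any(bad)) {
      abort("invalid inspection events (times outside trial or bad group size)",
            class = "shoalwatch_validation")
    }
  }
  dur <- if (n > 0) events$end_s - events$start_s else numeric(0)
  tpf <- if (n == 0) {
    0
  } else if (time_per_fish == "person_time") {
    sum(dur * events$group_size) / shoal_size
  } else {
    interval_union_length(events$start_s, events$end_s)
  }
  tibble::tibble(
    n_inspections = n,
    mean_duration_s = if (n > 0) mean(dur) else NA_real_,
    time_per_fish_s = tpf,
    occurred = n > 0,
    rate_per_hour = n / (duration_s / 3600)
  )
}

#' Build the per-trial response table
#'
#' Assembles the tidy table that feeds the mixed models: one row per trial
#' with its design factors, the inspection summaries, their standard
#' transforms (`log10(x + 1)` for the count and mean duration, square root
#' for time per fish), and — when trajectories are supplied — the
#' average-speed activity metric.
#'
#' @param trials List of trials as returned by [simulate_study()] (or built
#'   by hand): each element needs `events` and `info` (a one-row data frame
#'   of factors, including `shoal_size` if it varies) and may carry a
#'   `trajectory`.
#' @param duration_s Trial duration in seconds (default 1200).
#' @param with_speed Compute [average_speed()] per trial? (Default `FALSE`;
#'   it is the slow part.)
#' @return A tibble, one row per trial.
#' @export
build_response_table <- function(trials, duration_s = 1200, with_speed = FALSE) {
  stopifnot(is.list(trials), length(trials) >= 1)
  rows <- lapply(seq_along(trials), function(i) {
    t <- trials[[i]]
    info <- tibble::as_tibble(t$info %||% tibble::tibble())
    shoal <- if ("shoal_size" %in% names(info)) info$shoal_size[1] else 4
    s <- summarize_inspections(t$events, shoal_size = shoal, duration_s = duration_s)
    out <- dplyr::bind_cols(tibble::tibble(trial = i), info, s)
    out$log_n_inspections <- transform_response(s$n_inspections, "log_offset")
    out$log_mean_duration <- transform_response(
      ifelse(is.na(s$mean_duration_s), 0, s$mean_duration_s), "log_offset")
    out$sqrt_time_per_fish <- transform_response(s$time_per_fish_s, "power")
    if (with_speed && !is.null(t$trajectory)) {
      out$avg_speed_cm_s <- average_speed(t$trajectory)
    }
    out
  })
  dplyr::bind_rows(rows)
}

interval_union_length <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      tot <- tot + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  tot + (cur_e - cur_s)
}

#' Pooled inspection rate
#'
#' Inspections per hour across a set of trials, reported rounded to the
#' nearest integer (the convention for headline rates) together with the
#' unrounded quotient.
#'
#' @param total_inspections Total event count.
#' @param total_hours Total observation time in hours (> 0).
#' @return A list with `rate` (integer-rounded) and `rate_exact`.
#' @export
#' @examples
#' pooled_rate(1092, 48)$rate # 23
pooled_rate <- function(total_inspections, total_hours) {
  if (!is.finite(total_hours) || total_hours <= 0) {
    abort("total_hours must be positive", class = "shoalwatch_error")
  }
  r <- total_inspections / total_hours
  list(rate = as.integer(round(r)), rate_exact = r)
}

#' Response transforms for inspection variables
#'
#' The monotone transforms applied before model fitting: a shifted log for
#' count-like responses (number of inspections, mean duration) and a power
#' transform for time spent inspecting per fish.
#'
#' @param values Non-negative numeric vector.
#' @param kind `"log_offset"` or `"power"`.
#' @param base Logarithm base (default 10).
#' @param offset Added before the log (default 1, so zeros map to 0).
#' @param lambda Power exponent (default 0.5); must be positive when zeros
#'   are present.
#' @return Transformed numeric vector.
#' @export
#' @examples
#' transform_response(c(0, 9, 99), "log_offset") # 0 1 2
transform_response <- function(values, kind = c("log_offset", "power"),
                               base = 10, offset = 1, lambda = 0.5) {
  kind <- match.arg(kind)
  if (any(values < 0, na.rm = TRUE)) {
    abort("responses must be non-negative", class = "shoalwatch_error")
  }
  if (kind == "log_offset") {
    log(values + offset, base = base)
  } else {
    if (lambda <= 0 && any(values == 0, na.rm = TRUE)) {
      abort("non-positive power exponent with zeros present", class = "shoalwatch_error")
    }
    values^lambda
  }
}

#' Average swimming speed over a trial
#'
#' Mean per-frame displacement of matched consecutive detections divided by
#' the frame interval — directly proportional to total distance travelled per
#' fish. Because individuals are unidentified, detections of consecutive
#' frames are paired by greedy nearest-neighbour matching with a maximum jump
#' threshold; frames with missing detections (gaps) contribute nothing.
#'
#' @param traj An aligned [trajectory()].
#' @param max_jump_cm Largest plausible single-frame displacement (default 5
#'   cm); larger candidate matches are discarded as identity switches.
#' @return Average speed in cm/s; `NA` (with a warning) when no consecutive
#'   pair of frames can be matched.
#' @export
average_speed <- function(traj, max_jump_cm = 5) {
  stopifnot(inherits(traj, "shoal_traj"))
  fps <- traj_fps(traj)
  ok <- traj$valid & !is.na(traj$x) & !is.na(traj$y)
  sub <- traj[ok, , drop = FALSE]
  if (nrow(sub) < 2) {
    warn("no valid consecutive detections; average speed undefined")
    return(NA_real_)
  }
  sub <- sub[order(sub$frame), , drop = FALSE]
  frames <- split(seq_len(nrow(sub)), sub$frame)
  fidx <- as.integer(names(frames))
  total_d <- 0
  n_pairs <- 0L
  for (k in seq_len(length(frames) - 1L)) {
    if (fidx[k + 1L] != fidx[k] + 1L) next
    a <- frames[[k]]; b <- frames[[k + 1L]]
    ax <- sub$x[a]; ay <- sub$y[a]
    bx <- sub$x[b]; by <- sub$y[b]
    D <- sqrt(outer(ax, bx, "-")^2 + outer(ay, by, "-")^2)
    while (length(D) && min(D) <= max_jump_cm) {
      w <- arrayInd(which.min(D), dim(D))
      total_d <- total_d + D[w]
      n_pairs <- n_pairs + 1L
      D <- D[-w[1], -w[2], drop = FALSE]
    }
  }
  if (n_pairs == 0L) {
    warn("no matched consecutive detections within the jump threshold")
    return(NA_real_)
  }
  (total_d / n_pairs) * fps
}

#' Enumerate a fully crossed experimental design
#'
#' Cartesian product of the factor levels with a fixed number of groups
#' (shoals) per treatment cell, plus the derived totals: number of groups,
#' number of fish (groups per cell x sum of shoal sizes x number of
#' non-shoal-size cells), and fish per replicate selection line.
#'
#' @param factors Named list of factor levels; a numeric element named
#'   `shoal_size` is interpreted as the shoal sizes.
#' @param groups_per_cell Groups tested per treatment cell.
#' @param n_replicates Number of replicate selection lines the groups are
#'   split across (default 3).
#' @return A list with `design` (tibble, one row per treatment cell with
#'   `n_groups`) and `totals` (`n_groups`, `n_fish`, `n_fish_per_replicate`,
#'   `even_split`).
#' @export
#' @examples
#' enumerate_design(
#'   list(sex = c("F", "M"), brain_size = c("large", "small"),
#'        shoal_size = c(1, 2, 4)),
#'   groups_per_cell = 12
#' )$totals
enumerate_design <- function(factors, groups_per_cell = 1, n_replicates = 3) {
  stopifnot(is.list(factors), length(factors) >= 1,
            all(lengths(factors) >= 1), groups_per_cell >= 1)
  design <- do.call(tidyr::expand_grid, factors)
  design$n_groups <- groups_per_cell
  n_groups <- nrow(design) * groups_per_cell
  if ("shoal_size" %in% names(factors) && is.numeric(factors$shoal_size)) {
    other_cells <- nrow(design) / length(factors$shoal_size)
    n_fish <- groups_per_cell * sum(factors$shoal_size) * other_cells
  } else {
    n_fish <- NA_real_
  }
  per_rep <- n_fish / n_replicates
  even <- is.finite(per_rep) && abs(per_rep - round(per_rep)) < 1e-9
  if (is.finite(per_rep) && !even) {
    warn("fish do not split evenly across replicate lines")
  }
  list(design = design,
       totals = list(n_groups = n_groups, n_fish = n_fish,
                     n_fish_per_replicate = per_rep, even_split = even))
}
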