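#' Behavioural parameters for the shoal simulator
#'
#' Controls of the agent-based trial generator. Defaults emulate the
#' phenomenology of predator-confrontation trials: shoals hold an avoidance
#' ring about 10 cm from the model, launch saltatory inspection bouts at
#' around 23 per hour (about 32 per hour for shoals of four), approach the
#' flanks and rear far more often than the head, and occasionally freeze for
#' up to several minutes.
#'
#' @param cruise_speed_cm_s Baseline swimming speed (cm/s).
#' @param avoidance_radius_cm Preferred ring distance from the object (cm).
#' @param ring_tightness_cm Stationary sd of the preferred distance (cm).
#' @param inspection_rate_per_hour Poisson bout rate (events/h).
#' @param inspection_duration_mean_s,inspection_duration_sd_s Bout duration
#'   distribution (s), truncated below at 1 s.
#' @param inspection_approach_cm Closest approach during a bout (cm from the
#'   object centroid); must be smaller than the avoidance radius.
#' @param attack_cone_avoidance Probability that a bout targets the flanks or
#'   rear rather than the head cone (in `[0, 1]`).
#' @param freeze_prob_per_min Hazard of freeze onset (per fish per minute).
#' @param freeze_duration_mean_s,freeze_duration_max_s Exponential freeze
#'   duration mean and hard cap (s).
#' @param shoal_cohesion_cm Inter-individual distance beyond which a fish is
#'   pulled back toward the shoal centroid (cm).
#' @return An object of class `behaviour_params`.
#' @export
behaviour_params <- function(cruise_speed_cm_s = 8,
                             avoidance_radius_cm = 10,
                             ring_tightness_cm = 2,
                             inspection_rate_per_hour = 23,
                             inspection_duration_mean_s = 5,
                             inspection_duration_sd_s = 2,
                             inspection_approach_cm = 5,
                             attack_cone_avoidance = 0.8,
                             freeze_prob_per_min = 0.02,
                             freeze_duration_mean_s = 20,
                             freeze_duration_max_s = 180,
                             shoal_cohesion_cm = 8) {
  p <- list(cruise_speed_cm_s = cruise_speed_cm_s,
            avoidance_radius_cm = avoidance_radius_cm,
            ring_tightness_cm = ring_tightness_cm,
            inspection_rate_per_hour = inspection_rate_per_hour,
            inspection_duration_mean_s = inspection_duration_mean_s,
            inspection_duration_sd_s = inspection_duration_sd_s,
            inspection_approach_cm = inspection_approach_cm,
            attack_cone_avoidance = attack_cone_avoidance,
            freeze_prob_per_min = freeze_prob_per_min,
            freeze_duration_mean_s = freeze_duration_mean_s,
            freeze_duration_max_s = freeze_duration_max_s,
            shoal_cohesion_cm = shoal_cohesion_cm)
  nonneg <- unlist(p)
  if (any(!is.finite(nonneg)) || any(nonneg < 0)) {
    abort("behaviour parameters must be finite and non-negative", class = "shoalwatch_validation")
  }
  if (attack_cone_avoidance > 1) {
    abort("attack_cone_avoidance must lie in [0, 1]", class = "shoalwatch_validation")
  }
  if (inspection_approach_cm >= avoidance_radius_cm) {
    abort("inspection approach must be closer than the avoidance radius",
          class = "shoalwatch_validation")
  }
  structure(p, class = "behaviour_params")
}

# distance from the object centroid to its footprint boundary along an
# absolute direction (degrees), plus margin
footprint_clearance <- function(pose, angle_deg, margin = 0.5) {
  fp <- pose$footprint
  if (is.null(fp)) return(margin)
  th <- angle_deg * pi / 180
  probe <- seq(0.2, 30, by = 0.05)
  px <- pose$x_cm + probe * cos(th)
  py <- pose$y_cm + probe * sin(th)
  outside <- region_distance(px, py, fp) > 0
  if (!any(outside)) return(30)
  probe[which(outside)[1]] + margin
}

draw_bout_schedule <- function(params, pose, shoal_size, duration_s) {
  rate_s <- params$inspection_rate_per_hour / 3600
  starts <- numeric(0)
  if (rate_s > 0) {
    t <- rexp(1, rate_s)
    while (t < duration_s) {
      starts <- c(starts, t)
      t <- t + rexp(1, rate_s)
    }
  }
  n <- length(starts)
  if (n == 0) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0),
                          group_size = integer(0), target_x = numeric(0),
                          target_y = numeric(0)))
  }
  durs <- pmax(rnorm(n, params$inspection_duration_mean_s,
                     params$inspection_duration_sd_s), 1)
  ends <- pmin(starts + durs, duration_s)
  gsize <- sample.int(shoal_size, n, replace = TRUE)
  head_dir <- ifelse(is.na(pose$heading_deg), 0, pose$heading_deg)
  flank <- runif(n) < params$attack_cone_avoidance
  # head cone: +/- 45 deg about the heading; flank/rear: everything else
  ang <- ifelse(flank,
                (head_dir + runif(n, 45, 315)) %% 360,
                (head_dir + runif(n, -45, 45)) %% 360)
  tdist <- vapply(ang, function(a)
    max(params$inspection_approach_cm, footprint_clearance(pose, a)), numeric(1))
  tibble::tibble(start_s = starts, end_s = ends, group_size = gsize,
                 target_x = pose$x_cm + tdist * cos(ang * pi / 180),
                 target_y = pose$y_cm + tdist * sin(ang * pi / 180))
}

#' Simulate one arena trial
#'
#' Discrete-time stochastic shoal kinematics: a correlated walk holding an
#' avoidance ring around the stimulus object (distance relaxes toward the
#' preferred radius with stationary sd `ring_tightness_cm`), cohesion pull
#' toward the shoal centroid, Poisson-arriving inspection bouts during which
#' a random subgroup approaches a flank/rear (or, rarely, head) target and
#' returns, and freezes that suspend motion. All positions stay inside the
#' arena and outside the object footprint. Fully reproducible from the seed.
#'
#' @param params [behaviour_params()].
#' @param arena [arena_spec()].
#' @param pose Stimulus [object_pose()]; default: predator model at
#'   (12, 14.5) cm, heading 90 degrees.
#' @param shoal_size Number of fish (typical values 1, 2, 4).
#' @param duration_s Trial length in seconds (default 1200).
#' @param fps Frames per second (default 30).
#' @param seed Optional integer seed.
#' @return A list: `trajectory` (ground-truth [trajectory()], all valid),
#'   `events` (tibble `start_s`, `end_s`, `group_size`), `pose`, `params`.
#' @export
simulate_trial <- function(params = behaviour_params(), arena = arena_spec(),
                           pose = NULL, shoal_size = 4, duration_s = 1200,
                           fps = 30, seed = NULL) {
  stopifnot(inherits(params, "behaviour_params"), shoal_size >= 1)
  if (is.null(pose)) pose <- object_pose(12, arena$width_cm / 2, 90)
  run <- function() {
    n_frames <- round(duration_s * fps)
    bouts <- draw_bout_schedule(params, pose, shoal_size, duration_s)
    tx <- matrix(NA_real_, n_frames, shoal_size)
    ty <- matrix(NA_real_, n_frames, shoal_size)
    if (nrow(bouts) > 0) {
      for (b in seq_len(nrow(bouts))) {
        f0 <- floor(bouts$start_s[b] * fps)
        f1 <- min(ceiling(bouts$end_s[b] * fps), n_frames) - 1L
        if (f1 < f0) next
        fish <- sample.int(shoal_size, bouts$group_size[b])
        tx[(f0:f1) + 1L, fish] <- bouts$target_x[b]
        ty[(f0:f1) + 1L, fish] <- bouts$target_y[b]
      }
    }
    fp <- pose$footprint
    obj <- if (is.null(fp)) {
      c(pose$x_cm, pose$y_cm, 0, 0, 0)
    } else if (fp$type == "capsule") {
      c(fp$cx, fp$cy, fp$heading_deg, (fp$length_cm - fp$width_cm) / 2, fp$width_cm / 2)
    } else if (fp$type == "circle") {
      c(fp$cx, fp$cy, 0, 0, fp$radius)
    } else {
      abort("simulator supports capsule/circle/point footprints", class = "shoalwatch_validation")
    }
    par <- c(params$cruise_speed_cm_s, params$avoidance_radius_cm,
             params$ring_tightness_cm, params$shoal_cohesion_cm,
             params$freeze_prob_per_min / (60 * fps),
             params$freeze_duration_mean_s, params$freeze_duration_max_s)
    sim <- sim_trial_cpp(shoal_size, n_frames, fps, arena$length_cm, arena$width_cm,
                         obj, par, tx, ty)
    traj <- tibble::tibble(
      frame = rep(seq_len(n_frames) - 1L, times = shoal_size),
      point_id = rep(seq_len(shoal_size), each = n_frames),
      x = as.vector(sim$x), y = as.vector(sim$y), valid = TRUE
    )
    list(trajectory = trajectory(traj, fps = fps, duration_s = duration_s),
         events = bouts[, c("start_s", "end_s", "group_size")],
         pose = pose, params = params)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
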