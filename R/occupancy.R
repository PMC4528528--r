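#' Occupancy grid specification
#'
#' Tiles the arena with half-open square cells: cell (i, j), 0-based, covers
#' `[i*c, (i+1)*c) x [j*c, (j+1)*c)`.
#'
#' @param arena An [arena_spec()].
#' @return An object of class `grid_spec` with `n_x`, `n_y` cell counts.
#' @export
grid_spec <- function(arena = arena_spec()) {
  c_cm <- arena$grid_cell_cm
  structure(list(arena = arena, cell_cm = c_cm,
                 n_x = as.integer(round(arena$length_cm / c_cm)),
                 n_y = as.integer(round(arena$width_cm / c_cm))),
            class = "grid_spec")
}

grid_cells <- function(grid) {
  tidyr::expand_grid(iy = seq_len(grid$n_y) - 1L, ix = seq_len(grid$n_x) - 1L) |>
    dplyr::mutate(x = (.data$ix + 0.5) * grid$cell_cm,
                  y = (.data$iy + 0.5) * grid$cell_cm) |>
    dplyr::select("ix", "iy", "x", "y")
}

#' Per-trial occupancy density map
#'
#' Bins the valid, in-grid observations of one trial into the occupancy grid.
#' Each such observation contributes 1/n to exactly one cell, so the map is
#' the fraction of observations per cell and sums to 1. Invalid observations
#' and points outside the grid (e.g. carried out of the nominal arena by the
#' object overlay) are excluded from both numerator and denominator.
#'
#' @param traj An aligned [trajectory()].
#' @param grid A [grid_spec()].
#' @return A tibble of class `density_map` with one row per cell (`ix`, `iy`,
#'   cell-centre `x`, `y`, `density`); attributes `grid` and `n_valid_obs`.
#' @export
density_map <- function(traj, grid = grid_spec()) {
  stopifnot(inherits(traj, "shoal_traj"), inherits(grid, "grid_spec"))
  keep <- traj$valid & !is.na(traj$x) & !is.na(traj$y)
  x <- traj$x[keep]
  y <- traj$y[keep]
  ix <- floor(x / grid$cell_cm)
  iy <- floor(y / grid$cell_cm)
  ing <- ix >= 0 & ix < grid$n_x & iy >= 0 & iy < grid$n_y
  n <- sum(ing)
  if (n == 0) {
    abort("trial has no valid observation inside the grid", class = "shoalwatch_empty_trial")
  }
  idx <- iy[ing] * grid$n_x + ix[ing] + 1L
  counts <- tabulate(idx, nbins = grid$n_x * grid$n_y)
  out <- grid_cells(grid)
  out$density <- counts / n
  attr(out, "grid") <- grid
  attr(out, "n_valid_obs") <- n
  class(out) <- unique(c("density_map", class(out)))
  out
}

#' Stack per-trial density maps into one long table
#'
#' @param maps Named list of [density_map()]s (names become the `trial`
#'   column), or an already-long tibble with columns `trial`, `ix`, `iy`,
#'   `density`.
#' @return A long tibble; attribute `grid` is carried over.
#' @export
bind_density_maps <- function(maps) {
  if (is.data.frame(maps)) {
    stopifnot(all(c("trial", "ix", "iy", "density") %in% names(maps)))
    return(maps)
  }
  stopifnot(is.list(maps), length(maps) >= 1)
  if (is.null(names(maps))) names(maps) <- paste0("trial_", seq_along(maps))
  out <- dplyr::bind_rows(lapply(maps, tibble::as_tibble), .id = "trial")
  attr(out, "grid") <- attr(maps[[1]], "grid")
  out
}

# long/list of maps -> trials x cells matrix + cell table + grid
maps_matrix <- function(maps) {
  long <- bind_density_maps(maps)
  grid <- attr(long, "grid")
  long <- dplyr::arrange(long, .data$trial, .data$iy, .data$ix)
  trials <- unique(long$trial)
  ncell <- nrow(long) / length(trials)
  stopifnot(ncell == round(ncell))
  cells <- long[long$trial == trials[1], c("ix", "iy", "x", "y")]
  V <- matrix(long$density, nrow = length(trials), ncol = ncell, byrow = TRUE)
  if (is.null(grid)) {
    cell_cm <- sort(unique(cells$x))
    cell_cm <- if (length(cell_cm) > 1) diff(cell_cm[1:2]) else 2 * cells$x[1]
    grid <- grid_spec(arena_spec((max(cells$ix) + 1) * cell_cm,
                                 (max(cells$iy) + 1) * cell_cm, cell_cm))
  }
  list(V = V, cells = tibble::as_tibble(cells), grid = grid, trials = trials)
}

new_significance_map <- function(cells, p, direction, n, grid, test_kind) {
  out <- cells
  out$p <- p
  out$direction <- as.integer(direction)
  out$n <- n
  attr(out, "grid") <- grid
  attr(out, "test_kind") <- test_kind
  class(out) <- unique(c("significance_map", class(out)))
  out
}

#' Within-treatment occupancy significance map
#'
#' For every grid cell, tests whether trials of one treatment visited the
#' cell more or less than their baseline density, with a two-sided Wilcoxon
#' signed-rank test handling zero differences by the Pratt convention (zeros
#' ranked, then dropped). The default baseline is each trial's own median
#' cell density, so each trial contributes one paired difference per cell;
#' `"grand_median"` uses the pooled median of all cell densities instead.
#' Cells where every paired difference is zero are undefined (`p = NA`,
#' direction 0). No multiple-testing correction is applied by default:
#' the maps are read for large-scale patterns, not single cells; set
#' `adjust = "BH"` for a Benjamini-Hochberg-adjusted map.
#'
#' @param maps >= 2 per-trial density maps ([bind_density_maps()] input).
#' @param baseline `"trial_median"` (default) or `"grand_median"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `significance_map` tibble: `ix`, `iy`, `x`, `y`, `p`,
#'   `direction` (-1/0/+1), `n` (paired differences per cell).
#' @export
occupancy_significance <- function(maps, baseline = c("trial_median", "grand_median"),
                                   adjust = c("none", "BH")) {
  baseline <- match.arg(baseline)
  adjust <- match.arg(adjust)
  mm <- maps_matrix(maps)
  if (nrow(mm$V) < 2) {
    abort("occupancy significance needs at least 2 trials", class = "shoalwatch_sample_size")
  }
  base <- switch(baseline,
    trial_median = apply(mm$V, 1, median),
    grand_median = rep(median(mm$V), nrow(mm$V))
  )
  D <- mm$V - base
  res <- signed_rank_map_cpp(D)
  p <- res$p
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  new_significance_map(mm$cells, p, res$direction, res$m, mm$grid,
                       "occupancy_signed_rank")
}

# two-sided rank-sum p-values per cell; exact (pwilcox) when no ties and
# combined n <= 25; exact enumeration with midranks when the combined sample
# is small enough to enumerate (n <= 16) despite ties; otherwise normal
# approximation with tie + continuity correction
rank_sum_cells <- function(Va, Vb) {
  m <- nrow(Va)
  n <- nrow(Vb)
  N <- m + n
  X <- rbind(Va, Vb)
  R <- apply(X, 2, rank)
  W <- colSums(R[seq_len(m), , drop = FALSE])
  U <- W - m * (m + 1) / 2
  info <- ranksum_tie_info_cpp(X)
  p <- rep(NA_real_, ncol(X))
  method <- rep("normal", ncol(X))
  exact <- !info$any_tie & N <= 25
  if (any(exact)) {
    u <- U[exact]
    lo <- pwilcox(u, m, n)
    hi <- pwilcox(u - 1, m, n, lower.tail = FALSE)
    p[exact] <- pmin(1, 2 * pmin(lo, hi))
    method[exact] <- "exact"
  }
  enum <- !exact & N <= 16
  if (any(enum)) {
    p[enum] <- ranksum_exact_cpp(X[, enum, drop = FALSE], m)
    method[enum] <- "exact_ties"
  }
  rest <- !exact & !enum
  if (any(rest)) {
    u <- U[rest]
    ts <- info$tie_sum[rest]
    mu <- m * n / 2
    sig2 <- m * n / 12 * ((N + 1) - ts / (N * (N - 1)))
    z <- u - mu
    # continuity correction toward the mean
    z <- sign(z) * pmax(abs(z) - 0.5, 0)
    pv <- ifelse(sig2 > 0, 2 * pnorm(-abs(z / sqrt(sig2))), NA_real_)
    p[rest] <- pmin(pv, 1)
  }
  meda <- apply(Va, 2, median)
  medb <- apply(Vb, 2, median)
  dir <- sign(meda - medb)
  dir[is.na(p)] <- 0L
  list(p = p, direction = dir, method = method)
}

#' Between-group occupancy comparison map
#'
#' Per-cell two-sided Wilcoxon rank-sum test comparing the density values of
#' two groups of trials (e.g. the sexes, or the brain-size lines). Direction
#' is the sign of `median(A) - median(B)`. The exact null distribution is
#' used when the combined sample is at most 25 trials with no ties; small
#' tied samples (combined n at most 16) are enumerated exactly with
#' midranks; larger tied samples use the normal approximation with tie and
#' continuity corrections. The per-cell choice is recorded in the `method`
#' column.
#'
#' @param maps_a,maps_b Density maps of the two groups (>= 2 trials each), as
#'   lists or long tibbles sharing one grid.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `significance_map` with `test_kind` `"group_rank_sum"`.
#' @export
compare_groups <- function(maps_a, maps_b, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ma <- maps_matrix(maps_a)
  mb <- maps_matrix(maps_b)
  if (nrow(ma$V) < 2 || nrow(mb$V) < 2) {
    abort("each group needs at least 2 trials", class = "shoalwatch_sample_size")
  }
  stopifnot(ncol(ma$V) == ncol(mb$V))
  res <- rank_sum_cells(ma$V, mb$V)
  p <- res$p
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  out <- new_significance_map(ma$cells, p, res$direction,
                              rep(nrow(ma$V) + nrow(mb$V), ncol(ma$V)),
                              ma$grid, "group_rank_sum")
  out$method <- res$method
  attr(out, "n_a") <- nrow(ma$V)
  attr(out, "n_b") <- nrow(mb$V)
  out
}

#' Combine replicate comparison maps with Stouffer's z method
#'
#' Treats each replicate selection line as an independent experiment on the
#' same hypothesis: per cell, each replicate's two-sided p and direction are
#' converted to a signed normal quantile `z = direction * qnorm(1 - p/2)`,
#' summed, and divided by `sqrt(k)` (unweighted Stouffer). Cells undefined in
#' some replicates are combined over the defined subset (the effective k is
#' reported in `n`); cells undefined in every replicate stay undefined.
#'
#' @param per_replicate List of >= 2 `significance_map`s of kind
#'   `"group_rank_sum"` sharing one grid.
#' @return A `significance_map` with `test_kind` `"stouffer_combined"`.
#' @export
stratified_combine <- function(per_replicate) {
  stopifnot(is.list(per_replicate), length(per_replicate) >= 2)
  kinds <- vapply(per_replicate, function(m) attr(m, "test_kind"), character(1))
  if (!all(kinds == "group_rank_sum")) {
    abort("stratified_combine expects group rank-sum maps", class = "shoalwatch_error")
  }
  P <- do.call(cbind, lapply(per_replicate, function(m) m$p))
  Dir <- do.call(cbind, lapply(per_replicate, function(m) as.numeric(m$direction)))
  Z <- Dir * qnorm(pmin(pmax(P, 1e-300), 1) / 2, lower.tail = FALSE)
  defined <- !is.na(P)
  Z[!defined] <- 0
  k <- rowSums(defined)
  Zc <- ifelse(k > 0, rowSums(Z) / sqrt(pmax(k, 1)), NA_real_)
  p <- ifelse(k > 0, pmin(2 * pnorm(-abs(Zc)), 1), NA_real_)
  dir <- sign(Zc)
  dir[is.na(p)] <- 0
  new_significance_map(per_replicate[[1]][, c("ix", "iy", "x", "y")],
                       p, dir, as.integer(k),
                       attr(per_replicate[[1]], "grid"), "stouffer_combined")
}

#' Split a trajectory into consecutive time windows
#'
#' Non-overlapping windows of `window_s` seconds, preserving all flags and
#' original frame indices; concatenating the windows reproduces the input.
#' A final partial window is kept, with a warning, when `window_s` does not
#' divide the trial duration.
#'
#' @param traj A [trajectory()].
#' @param window_s Window length in seconds (> 0).
#' @return A list of trajectories; each carries attributes `window_start_s`
#'   and its own (possibly truncated) duration.
#' @export
time_windows <- function(traj, window_s) {
  stopifnot(inherits(traj, "shoal_traj"))
  if (!is.finite(window_s) || window_s <= 0) {
    abort("window_s must be positive", class = "shoalwatch_error")
  }
  fps <- traj_fps(traj)
  dur <- traj_duration(traj)
  n_win <- ceiling(dur / window_s - 1e-9)
  if (abs(dur / window_s - round(dur / window_s)) > 1e-9) {
    warn("window_s does not divide the trial duration; last window truncated")
  }
  wpf <- round(window_s * fps)
  lapply(seq_len(n_win) - 1L, function(k) {
    lo <- k * wpf
    hi <- min((k + 1) * wpf, round(dur * fps))
    out <- traj[traj$frame >= lo & traj$frame < hi, , drop = FALSE]
    out <- new_trajectory(out, fps = fps, duration_s = (hi - lo) / fps)
    attr(out, "window_start_s") <- lo / fps
    out
  })
}

#' Ring-distance estimate from a significance map
#'
#' Summarises an avoidance ring in an occupancy significance map: among cells
#' significant at `alpha` with the requested direction, the distance to the
#' object centroid whose distance bin holds the highest *fraction* of
#' significant cells (fraction, not count, so the estimate is not inflated by
#' the growing number of cells in wider annuli). Ties between maximal bins
#' are resolved by their median distance.
#'
#' @param sig_map A `significance_map`.
#' @param pose The reference [object_pose()] the trials were aligned to.
#' @param alpha Significance level (default 0.05).
#' @param direction Which direction marks the ring (+1 = visited more than
#'   baseline).
#' @param bin_cm Distance-bin width; defaults to the grid cell size.
#' @return The modal ring distance in cm (`NA` when no cell is significant).
#' @export
estimate_ring_distance <- function(sig_map, pose, alpha = 0.05, direction = 1,
                                   bin_cm = NULL) {
  stopifnot(inherits(sig_map, "significance_map"))
  grid <- attr(sig_map, "grid")
  if (is.null(bin_cm)) bin_cm <- grid$cell_cm
  d <- sqrt((sig_map$x - pose$x_cm)^2 + (sig_map$y - pose$y_cm)^2)
  bin <- floor(d / bin_cm)
  sig <- !is.na(sig_map$p) & sig_map$p < alpha & sig_map$direction == direction
  if (!any(sig)) return(NA_real_)
  tot <- tapply(rep(1, length(bin)), bin, sum)
  hit <- tapply(as.numeric(sig), bin, sum)
  frac <- hit / tot
  frac[tot < 3] <- 0 # ignore nearly empty annuli
  best <- which(frac == max(frac))
  (median(as.numeric(names(frac)[best])) + 0.5) * bin_cm
}
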