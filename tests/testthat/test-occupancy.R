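test_that("density maps are normalised visit fractions binned exactly", {
  grid <- grid_spec()
  # all observations in one cell
  tr <- trajectory(tibble::tibble(frame = 0:9, x = 10.1, y = 10.1), 30, 1)
  dm <- density_map(tr, grid)
  expect_equal(max(dm$density), 1)
  expect_equal(sum(dm$density > 0), 1)
  # two observations in two cells
  tr <- trajectory(tibble::tibble(frame = 0:1, x = c(1.1, 20.1), y = 5), 30, 1)
  dm <- density_map(tr, grid)
  expect_equal(sort(dm$density[dm$density > 0]), c(0.5, 0.5))
  # full seeded simulation matches the histogram oracle exactly
  sim <- quick_trial(11, shoal_size = 4, duration_s = 120, fps = 30)
  dm <- density_map(sim$trajectory, grid)
  M <- oracle_density(sim$trajectory$x, sim$trajectory$y, 0.5, grid$n_x, grid$n_y)
  got <- matrix(dm$density[order(dm$iy, dm$ix)], grid$n_y, grid$n_x, byrow = TRUE)
  expect_identical(got, M)
  expect_equal(sum(dm$density), 1, tolerance = 1e-12)
})

test_that("invalid and out-of-grid observations are excluded from both sides of the fraction", {
  grid <- grid_spec()
  tr <- trajectory(tibble::tibble(frame = 0:3, x = c(10, 10, -5, 10), y = 10,
                                  valid = c(TRUE, TRUE, TRUE, FALSE)), 30, 1)
  dm <- density_map(tr, grid)
  expect_equal(attr(dm, "n_valid_obs"), 2)
  expect_equal(max(dm$density), 1) # the two valid in-grid points share a cell
  # no valid observation -> empty-trial error
  none <- trajectory(tibble::tibble(frame = 0, x = 10, y = 10, valid = FALSE), 30, 1)
  expect_error(density_map(none, grid), class = "shoalwatch_empty_trial")
})

test_that("adding an observation to a cell never decreases its density", {
  grid <- grid_spec()
  set.seed(31)
  base <- tibble::tibble(frame = 0:99, x = runif(100, 0, 59), y = runif(100, 0, 29))
  dm0 <- density_map(trajectory(base, 30, 10), grid)
  extra <- dplyr::bind_rows(base, tibble::tibble(frame = 100, x = 10.1, y = 10.1))
  dm1 <- density_map(trajectory(extra, 30, 10), grid)
  cell <- dm0$ix == 20 & dm0$iy == 20
  expect_gte(dm1$density[cell], dm0$density[cell])
})

test_that("occupancy signed-rank maps handle degenerate ties and known exact cases", {
  grid <- grid_spec(arena_spec(5, 5, 0.5)) # 100 cells
  n_cells <- 100
  # identical uniform trials: every paired difference zero -> p undefined
  V <- matrix(1 / n_cells, nrow = 4, ncol = n_cells)
  sig <- occupancy_significance(fake_maps(V, grid))
  expect_true(all(is.na(sig$p)))
  expect_true(all(sig$direction == 0))
  # six trials with cell 1 at five times their median: p = 2/2^6 = 0.03125
  set.seed(12)
  V <- t(replicate(6, runif(n_cells, 0.5, 1.5)))
  V[, 1] <- 5 * apply(V, 1, median)
  sig <- occupancy_significance(fake_maps(V, grid))
  expect_equal(sig$p[sig$ix == 0 & sig$iy == 0], 0.03125)
  expect_equal(sig$direction[sig$ix == 0 & sig$iy == 0], 1L)
  # fewer than two trials is a sample-size error
  expect_error(occupancy_significance(fake_maps(V[1, , drop = FALSE], grid)),
               class = "shoalwatch_sample_size")
})

test_that("group comparison maps are symmetric and exact in the known separation case", {
  grid <- grid_spec(arena_spec(5, 5, 0.5))
  set.seed(13)
  Va <- t(replicate(4, runif(100)))
  Vb <- t(replicate(4, runif(100)))
  ab <- compare_groups(fake_maps(Va, grid), fake_maps(Vb, grid))
  ba <- compare_groups(fake_maps(Vb, grid), fake_maps(Va, grid))
  expect_equal(ab$p, ba$p)
  expect_equal(ab$direction, -ba$direction)
  # complete separation 4 vs 4, zeros against positives: exact p = 2/70
  Va0 <- Va; Va0[, 1] <- 0
  Vb1 <- Vb; Vb1[, 1] <- c(0.1, 0.2, 0.3, 0.4)
  sep <- compare_groups(fake_maps(Va0, grid), fake_maps(Vb1, grid))
  expect_equal(sep$p[sep$ix == 0 & sep$iy == 0], 2 / 70, tolerance = 1e-12)
  expect_equal(sep$direction[sep$ix == 0 & sep$iy == 0], -1L)
  # self-comparison: defined p all 1, direction 0
  self <- compare_groups(fake_maps(Va, grid), fake_maps(Va, grid))
  expect_true(all(self$p[!is.na(self$p)] == 1))
  expect_true(all(self$direction == 0))
  expect_error(compare_groups(fake_maps(Va[1, , drop = FALSE], grid), fake_maps(Vb, grid)),
               class = "shoalwatch_sample_size")
})

test_that("Stouffer combination follows its closed form and bookkeeping rules", {
  # three replicates at p = 0.05, same direction
  comb <- stratified_combine(lapply(1:3, function(i) tiny_sig_map(0.05, 1)))
  z <- qnorm(0.025, lower.tail = FALSE)
  expect_equal(comb$p, 2 * pnorm(-z * sqrt(3)), tolerance = 1e-10)
  expect_equal(comb$p, 6.86e-4, tolerance = 1e-2)
  expect_equal(comb$direction, 1L)
  # equal p, opposite directions cancel to p = 1
  comb <- stratified_combine(list(tiny_sig_map(0.05, 1), tiny_sig_map(0.05, -1)))
  expect_equal(comb$p, 1)
  expect_equal(comb$direction, 0L)
  # a cell defined in a single replicate keeps that replicate's p
  comb <- stratified_combine(list(tiny_sig_map(0.0321, -1), tiny_sig_map(NA_real_, 0)))
  expect_equal(comb$p, 0.0321, tolerance = 1e-12)
  expect_equal(comb$n, 1L)
  # all replicates undefined -> undefined, not an error
  comb <- stratified_combine(list(tiny_sig_map(NA_real_, 0), tiny_sig_map(NA_real_, 0)))
  expect_true(is.na(comb$p))
  expect_equal(comb$direction, 0)
  # combining k identical maps scales |z| by sqrt(k), cell-wise
  grid <- grid_spec(arena_spec(5, 5, 0.5))
  set.seed(14)
  Va <- t(replicate(3, runif(100)))
  Vb <- t(replicate(3, runif(100)))
  one <- compare_groups(fake_maps(Va, grid), fake_maps(Vb, grid))
  comb <- stratified_combine(list(one, one, one))
  def <- !is.na(one$p) & one$p < 1 & one$direction != 0
  z1 <- abs(qnorm(one$p[def] / 2, lower.tail = FALSE))
  zc <- abs(qnorm(comb$p[def] / 2, lower.tail = FALSE))
  expect_equal(zc, sqrt(3) * z1, tolerance = 1e-8)
  # only rank-sum maps are combinable
  om <- occupancy_significance(fake_maps(Va, grid))
  expect_error(stratified_combine(list(om, om)), class = "shoalwatch_error")
})

test_that("time windows partition a trial without losing observations", {
  tr <- simulate_trial(duration_s = 1200, fps = 30, shoal_size = 1, seed = 9)$trajectory
  w <- time_windows(tr, 300)
  expect_length(w, 4)
  expect_true(all(vapply(w, nrow, integer(1)) == 9000))
  expect_true(all(vapply(w, traj_duration, numeric(1)) == 300))
  # concatenation reproduces the input
  expect_equal(dplyr::bind_rows(lapply(w, as.data.frame)),
               as.data.frame(tr), ignore_attr = TRUE)
  # window equal to full duration: singleton equal to input
  w1 <- time_windows(tr, 1200)
  expect_length(w1, 1)
  expect_equal(as.data.frame(w1[[1]]), as.data.frame(tr), ignore_attr = TRUE)
  # valid counts are conserved across windows
  expect_equal(sum(vapply(w, function(x) sum(x$valid), numeric(1))), sum(tr$valid))
  # non-dividing window warns and truncates
  expect_warning(w5 <- time_windows(tr, 450), "truncated")
  expect_length(w5, 3)
  expect_error(time_windows(tr, 0), class = "shoalwatch_error")
})
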