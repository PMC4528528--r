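test_that("homography fitting recovers identity, translation, and random transforms", {
  corners <- arena_corners()
  # identity
  h <- fit_homography(corners, corners)
  expect_equal(unclass(h), diag(3), tolerance = 1e-9)
  # pure translation
  h <- fit_homography(corners, corners + rep(c(3, 1), each = 4))
  expect_equal(unclass(h), matrix(c(1, 0, 3, 0, 1, 1, 0, 0, 1), 3, 3, byrow = TRUE),
               tolerance = 1e-9)
  # round trip on a synthetic homography: fit on mapped corners recovers it
  set.seed(101)
  for (rep in 1:5) {
    Hstar <- random_homography()
    rect <- rbind(c(0, 0), c(59, 0), c(59, 29), c(0, 29))
    mapped <- oracle_apply_homography(rect, Hstar)
    h <- fit_homography(rect, mapped)
    expect_equal(unclass(h) / h[3, 3], Hstar / Hstar[3, 3], tolerance = 1e-6)
    # residuals on interior points
    pts <- cbind(runif(1000, 0, 59), runif(1000, 0, 29))
    got <- apply_homography(pts, h)
    want <- oracle_apply_homography(pts, Hstar)
    expect_lt(max(abs(cbind(got$x, got$y) - want)), 1e-6)
  }
})

test_that("corner fitting maps each source corner onto its target within tolerance", {
  set.seed(7)
  Hstar <- random_homography()
  src <- rbind(c(2, 3), c(50, 1), c(55, 27), c(1, 25))
  dst <- oracle_apply_homography(src, Hstar)
  h <- fit_homography(src, dst)
  got <- apply_homography(src, h)
  expect_lt(max(abs(cbind(got$x, got$y) - dst)), 1e-9)
})

test_that("degenerate (collinear) corner configurations raise a geometry error", {
  src <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 5))
  expect_error(fit_homography(src, arena_corners()), class = "shoalwatch_geometry_error")
})

test_that("apply_homography follows the homogeneous conventions", {
  pts <- cbind(runif(20, -5, 5), runif(20, -5, 5))
  # identity leaves points unchanged
  got <- apply_homography(pts, diag(3))
  expect_equal(cbind(got$x, got$y), pts, ignore_attr = TRUE)
  # translation
  Ht <- matrix(c(1, 0, 2, 0, 1, 5, 0, 0, 1), 3, 3, byrow = TRUE)
  got <- apply_homography(cbind(0, 0), Ht)
  expect_equal(c(got$x, got$y), c(2, 5))
  # composition law: apply(apply(p, A), B) == apply(p, B %*% A)
  set.seed(21)
  A <- random_homography()
  B <- random_homography()
  one <- apply_homography(pts, A)
  two <- apply_homography(cbind(one$x, one$y), B)
  direct <- apply_homography(pts, B %*% A)
  expect_equal(cbind(two$x, two$y), cbind(direct$x, direct$y), tolerance = 1e-9)
  # per-point oracle, exact agreement
  grid100 <- as.matrix(expand.grid(x = seq(0, 59, length.out = 10),
                                   y = seq(0, 29, length.out = 10)))
  got <- apply_homography(grid100, A)
  expect_equal(cbind(got$x, got$y), oracle_apply_homography(grid100, A),
               ignore_attr = TRUE)
  # a point sent to infinity is flagged invalid, not an error
  Hbad <- matrix(c(1, 0, 0, 0, 1, 0, -1, 0, 1), 3, 3, byrow = TRUE) # w = 1 - x
  got <- apply_homography(rbind(c(1, 0), c(2, 2)), Hbad)
  expect_false(got$valid[1])
  expect_true(got$valid[2])
  expect_true(is.na(got$x[1]))
})

test_that("rigid alignment overlays poses and preserves distances", {
  tr <- quick_trial(1, shoal_size = 4)
  ref <- object_pose(12, 14.5, 90)
  # identity alignment
  same <- align_trajectory(tr$trajectory, ref, ref)
  expect_equal(same$x, tr$trajectory$x, tolerance = 1e-12)
  # pure translation: observed offset by (1, -2) -> points shifted by (-1, 2)
  obs <- object_pose(13, 12.5, 90)
  shifted <- align_trajectory(tr$trajectory, obs, ref)
  expect_equal(shifted$x, tr$trajectory$x - 1, tolerance = 1e-9)
  expect_equal(shifted$y, tr$trajectory$y + 2, tolerance = 1e-9)
  # 90-degree rotation: pairwise distances of simultaneous points unchanged
  obs <- object_pose(12, 14.5, 0)
  rot <- align_trajectory(tr$trajectory, obs, ref)
  f <- tr$trajectory$frame == 17
  before <- dist(cbind(tr$trajectory$x[f], tr$trajectory$y[f]))
  after <- dist(cbind(rot$x[f], rot$y[f]))
  expect_equal(as.numeric(after), as.numeric(before), tolerance = 1e-9)
  # point-to-object-centroid distances preserved too
  d0 <- sqrt((tr$trajectory$x - obs$x_cm)^2 + (tr$trajectory$y - obs$y_cm)^2)
  d1 <- sqrt((rot$x - ref$x_cm)^2 + (rot$y - ref$y_cm)^2)
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("missing heading falls back to translation-only overlay with a warning", {
  tr <- quick_trial(2)
  obs <- object_pose(13, 14.5, NA)
  ref <- object_pose(12, 14.5, 90)
  expect_warning(out <- align_trajectory(tr$trajectory, obs, ref), "rotation skipped")
  expect_equal(out$x, tr$trajectory$x - 1, tolerance = 1e-12)
})

test_that("rectification then alignment equals the composed transform applied once", {
  tr <- quick_trial(3)
  set.seed(5)
  H <- random_homography()
  cam <- rectify_trajectory(tr$trajectory, invert_homography(structure(H, class = "homography")))
  obs <- object_pose(13.5, 13.5, 70)
  ref <- object_pose(12, 14.5, 90)
  stepwise <- align_trajectory(rectify_trajectory(cam, H), obs, ref)
  composed <- unclass(rigid_from_poses(obs, ref)) %*% H
  direct <- apply_homography(cbind(cam$x, cam$y), composed)
  expect_equal(stepwise$x, direct$x, tolerance = 1e-9)
  expect_equal(stepwise$y, direct$y, tolerance = 1e-9)
})

test_that("mask regions implement the missing-data policy exactly and idempotently", {
  tr <- quick_trial(4)$trajectory
  # empty list: unchanged, nothing masked
  out <- mask_trajectory(tr, list())
  expect_equal(out$valid, tr$valid)
  expect_equal(sum(attr(out, "mask_counts")$n), 0)
  # whole arena: everything masked
  whole <- mask_region(region_rect(-1, 60, -1, 30), "other", "missing")
  out <- mask_trajectory(tr, list(whole))
  expect_true(all(!out$valid))
  expect_equal(attr(out, "mask_counts")$n, nrow(tr))
  # planted fraction: build a trajectory with exactly 10% of points in a ledge
  n <- 1000
  x <- c(runif(0.9 * n, 0, 50), runif(0.1 * n, 57, 59))
  built <- trajectory(tibble::tibble(frame = seq_len(n) - 1, x = x, y = runif(n, 0, 29)),
                      fps = 30, duration_s = n / 30)
  ledge <- mask_region(region_rect(56, 59, 0, 29), "ledge", "missing")
  masked <- mask_trajectory(built, list(ledge))
  expect_equal(mean(!masked$valid), 0.10)
  # idempotence
  twice <- mask_trajectory(masked, list(ledge))
  expect_identical(twice$valid, masked$valid)
  expect_identical(twice$at_object, masked$at_object)
  # lowest-bin policy keeps validity but sets the at-object flag
  over <- mask_region(region_circle(10, 10, 3), "over_object", "lowest_bin_for_distance")
  flagged <- mask_trajectory(built, list(over))
  inside <- in_region(built$x, built$y, over$region)
  expect_identical(flagged$at_object, inside)
  expect_identical(flagged$valid, built$valid)
})
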