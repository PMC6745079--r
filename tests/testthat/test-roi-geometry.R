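box_mask <- function(dim, from, to, ...) {
  g <- array(FALSE, dim)
  g[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  voxel_mask(g, ...)
}

test_that("ROI mean curve averages masked voxels per echo", {
  sch <- standard_schedules()$abbreviated
  dm <- c(8, 8, 8)
  mask <- box_mask(dm, c(3, 3, 3), c(5, 5, 5))
  # uniform volumes -> constant curve
  vols <- lapply(seq_along(sch$all_tes), function(i) array(i / 10, dm))
  cv <- roi_mean_curve(vols, mask, sch)
  expect_equal(cv$signals, seq_along(sch$all_tes) / 10)
  # two-voxel mask -> arithmetic mean
  m2 <- voxel_mask(array(FALSE, dm))
  m2$grid[1, 1, 1] <- TRUE; m2$grid[2, 1, 1] <- TRUE
  v <- array(0, dm); v[1, 1, 1] <- 3; v[2, 1, 1] <- 5
  cv2 <- roi_mean_curve(rep(list(v), 6), m2, sch)
  expect_equal(cv2$signals, rep(4, 6))
  expect_error(roi_mean_curve(vols, voxel_mask(array(FALSE, dm)), sch),
               "empty")
  expect_error(roi_mean_curve(vols[1:3], mask, sch), "one volume per")
})

test_that("interface shell is a Euclidean ball dilation minus the graft", {
  dm <- c(11, 11, 11)
  single <- voxel_mask(array(FALSE, dm))
  single$grid[6, 6, 6] <- TRUE
  shell <- grow_interface(single, radius_mm = 2)
  # enumeration oracle: lattice points with 0 < d <= 2
  expect_equal(sum(shell$grid), oracle_ball_count(2))
  expect_equal(sum(shell$grid & single$grid), 0L)
  # radius equal to the voxel size gives the 6-connected shell
  shell1 <- grow_interface(single, radius_mm = 1)
  expect_equal(sum(shell1$grid), 6L)
  # a cube grows a shell that never overlaps it, on any radius
  cube <- box_mask(dm, c(5, 5, 5), c(7, 7, 7))
  for (r in c(1, 2, 3)) {
    sh <- grow_interface(cube, radius_mm = r)
    expect_equal(sum(sh$grid & cube$grid), 0L)
    expect_gt(sum(sh$grid), 0L)
  }
  expect_error(grow_interface(voxel_mask(array(FALSE, dm))), "empty")
  expect_error(grow_interface(single, radius_mm = 0.5), "at least one")
})

test_that("interface dilation respects anisotropic voxels and in-plane mode", {
  dm <- c(9, 9, 9)
  single <- voxel_mask(array(FALSE, dm), voxel_size = c(1, 1, 2))
  single$grid[5, 5, 5] <- TRUE
  shell <- grow_interface(single, radius_mm = 2)
  expect_equal(sum(shell$grid), oracle_ball_count(2, c(1, 1, 2)))
  iso <- voxel_mask(array(FALSE, dm)); iso$grid[5, 5, 5] <- TRUE
  inpl <- grow_interface(iso, radius_mm = 2, in_plane = TRUE)
  vox <- which(inpl$grid, arr.ind = TRUE)
  expect_true(all(vox[, 3] == 5))
})

test_that("angle to B0 handles axis-aligned and oblique geometries", {
  dm <- c(15, 15, 15)
  # column along B0 -> 0 degrees
  col <- voxel_mask(array(FALSE, dm))
  col$grid[8, 8, 3:12] <- TRUE
  expect_equal(angle_to_b0(col), 0, tolerance = 1e-9)
  # one-voxel x-shift per 1 mm slice -> 45 degrees
  stair <- voxel_mask(array(FALSE, dm))
  for (z in 3:12) stair$grid[z, 8, z] <- TRUE
  expect_equal(angle_to_b0(stair), 45, tolerance = 1e-9)
  expect_error(angle_to_b0(box_mask(dm, c(3, 3, 5), c(8, 8, 5))),
               ">= 2 slices")
})

test_that("angle matches an independent eigen-decomposition oracle", {
  dm <- c(21, 21, 21)
  set.seed(5)
  m <- voxel_mask(array(FALSE, dm))
  zs <- 4:17
  xs <- round(5 + 0.6 * (zs - 4) + c(0, diff(sin(zs))))  # noisy oblique path
  for (i in seq_along(zs)) m$grid[xs[i], 10, zs[i]] <- TRUE
  cent <- t(sapply(zs, function(z) {
    v <- which(m$grid[, , z, drop = FALSE], arr.ind = TRUE)
    c(mean(v[, 1]), mean(v[, 2]), z)
  }))
  expect_equal(angle_to_b0(m), oracle_principal_angle(cent),
               tolerance = 1e-8)
})

test_that("angle is invariant to translation and axis reflection", {
  dm <- c(21, 21, 21)
  m <- voxel_mask(array(FALSE, dm))
  for (z in 5:14) m$grid[z - 2, 9, z] <- TRUE
  a0 <- angle_to_b0(m)
  # translation
  mt <- voxel_mask(array(FALSE, dm))
  for (z in 5:14) mt$grid[z + 1, 12, z + 2] <- TRUE
  expect_equal(angle_to_b0(mt), a0, tolerance = 1e-9)
  # reflection through the y-z plane (x -> dim - x + 1)
  mr <- voxel_mask(m$grid[dim(m$grid)[1]:1, , ])
  expect_equal(angle_to_b0(mr), a0, tolerance = 1e-9)
})

test_that("dice coefficient follows the overlap formula", {
  dm <- c(10, 10, 10)
  a <- box_mask(dm, c(1, 1, 1), c(5, 10, 10))   # 500 voxels
  expect_equal(dice(a, a), 1)
  b <- box_mask(dm, c(6, 1, 1), c(10, 10, 10))  # disjoint 500
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100, |A n B| = 80 -> 0.8
  a1 <- box_mask(dm, c(1, 1, 1), c(10, 10, 1))
  b1 <- voxel_mask(array(FALSE, dm))
  b1$grid[, , 1] <- TRUE
  b1$grid[1:2, , 1] <- FALSE
  b1$grid[1:2, , 2] <- TRUE
  expect_equal(sum(a1$grid), 100)
  expect_equal(sum(b1$grid), 100)
  expect_equal(dice(a1, b1), 0.8)
  expect_true(dice(a, b) == dice(b, a))
  expect_error(dice(voxel_mask(array(FALSE, dm)),
                    voxel_mask(array(FALSE, dm))), "empty")
  expect_error(dice(a, box_mask(c(5, 5, 5), c(1, 1, 1), c(2, 2, 2))),
               "same grid")
})

test_that("intra-rater relative error is symmetric with the mean denominator", {
  e1 <- list(t2s = 1.0, f_bw = 0.85)
  e2 <- list(t2s = 1.1, f_bw = 0.85)
  err <- intra_rater_error(e1, e2)
  expect_equal(unname(err["t2s_pct"]), 100 * 0.1 / 1.05)  # 9.5238...
  expect_equal(unname(err["f_bw_pct"]), 0)
  expect_equal(intra_rater_error(e1, e2), intra_rater_error(e2, e1))
  expect_equal(unname(intra_rater_error(e1, e1)), c(0, 0))
  expect_error(intra_rater_error(list(t2s = -1, f_bw = 0.5), e1),
               "positive")
})

test_that("masks and volumes round-trip through NIfTI", {
  dm <- c(12, 10, 8)
  m <- box_mask(dm, c(2, 2, 2), c(6, 5, 4), voxel_size = c(1, 1, 1))
  f <- tempfile(fileext = ".nii.gz")
  write_mask_nifti(m, f)
  m2 <- read_mask_nifti(f)
  expect_equal(m2$grid, m$grid)
  expect_equal(m2$voxel_size, c(1, 1, 1))
  v <- array(rnorm(prod(dm)), dm)
  fv <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(v, fv)
  v2 <- read_volume_nifti(fv)
  expect_equal(as.numeric(v2), as.numeric(v), tolerance = 1e-6)
  unlink(c(f, fv))
})
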