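test_that("NIfTI round trip preserves grid, spacing and alignment", {
  tc <- make_toy_case()
  d <- withr::local_tempdir()
  ip <- file.path(d, "img.nii.gz"); mp <- file.path(d, "msk.nii.gz")
  write_nifti_volume(tc$volume, ip)
  write_nifti_volume(tc$mask, mp)
  rc <- read_case(ip, mp)
  expect_identical(dim(rc$volume$voxels), dim(tc$volume$voxels))
  expect_equal(rc$volume$spacing, tc$volume$spacing, tolerance = 1e-5)
  expect_equal(rc$volume$voxels, tc$volume$voxels, ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_identical(rc$mask$voxels, tc$mask$voxels)
})

test_that("read_case rejects empty masks and mismatched grids", {
  tc <- make_toy_case()
  d <- withr::local_tempdir()
  ip <- file.path(d, "img.nii.gz")
  write_nifti_volume(tc$volume, ip)
  empty <- roi_mask(array(0L, dim(tc$mask$voxels)), tc$mask$spacing)
  mp0 <- file.path(d, "empty.nii.gz")
  write_nifti_volume(empty, mp0)
  expect_error(read_case(ip, mp0), "empty mask")
  small <- roi_mask(array(1L, c(6, 6, 3)), tc$mask$spacing)
  mps <- file.path(d, "small.nii.gz")
  write_nifti_volume(small, mps)
  expect_error(read_case(ip, mps), "grid mismatch")
})

test_that("resampling to the source spacing is the identity and constants are preserved", {
  set.seed(1)
  v <- ct_volume(array(rnorm(10 * 12 * 6, 40, 20), c(10, 12, 6)),
                 c(0.8, 0.8, 2.5))
  same <- resample_volume(v, v$spacing)
  expect_equal(same$voxels, v$voxels, tolerance = 1e-6)
  const <- ct_volume(array(17, c(8, 8, 4)), c(1, 1, 2))
  rs <- resample_volume(const, c(0.6, 1.3, 1))
  expect_equal(range(rs$voxels), c(17, 17), tolerance = 1e-9)
  expect_equal(rs$spacing, c(0.6, 1.3, 1))
  expect_error(resample_volume(ct_volume(array(1, c(1, 5, 5)), c(1, 1, 1)),
                               c(1, 1, 1)), "degenerate")
})

test_that("downsampling a linear ramp matches the closed-form interpolant", {
  nx <- 17L
  ramp <- array(rep(seq_len(nx) - 1, times = 6 * 4), c(nx, 6, 4))
  v <- ct_volume(ramp, c(1, 1, 1))
  out <- resample_volume(v, c(2, 1, 1))
  ## linear interpolation of a linear function is exact: value at physical
  ## position x equals x / dx_in
  expected <- pmin((seq_len(dim(out$voxels)[1]) - 1) * 2, nx - 1)
  expect_equal(out$voxels[, 3, 2], expected, tolerance = 1e-12)
  ## physical extent preserved to within one voxel
  ext_in <- (nx - 1) * 1
  ext_out <- (dim(out$voxels)[1] - 1) * 2
  expect_lte(abs(ext_in - ext_out), 2)
})

test_that("window normalization maps bounds, midpoint, and clips", {
  w <- window_spec()
  expect_equal(window_normalize(array(c(-150, 150, 0, -500, 400), c(5, 1, 1)) |>
                                  ct_volume(c(1, 1, 1)), w)$voxels[, 1, 1],
               c(0, 1, 0.5, 0, 1))
  expect_error(window_spec(10, 10))
  ## monotone non-decreasing in HU
  x <- seq(-300, 300, by = 7)
  y <- window_normalize(ct_volume(array(x, c(length(x), 1, 1)), c(1, 1, 1)), w)
  expect_true(all(diff(y$voxels[, 1, 1]) >= 0))
})

test_that("largest-slice selection maximizes area with lowest-index ties", {
  msk <- array(0L, c(9, 5, 5))
  per_slice <- c(0L, 5L, 9L, 9L, 2L)
  for (k in 1:5) if (per_slice[k] > 0) msk[seq_len(per_slice[k]), 1, k] <- 1L
  expect_identical(select_largest_slice(roi_mask(msk, c(1, 1, 1))), 3L)
  one <- array(0L, c(4, 4, 6)); one[2, 2, 4] <- 1L
  expect_identical(select_largest_slice(roi_mask(one, c(1, 1, 1))), 4L)
  expect_error(select_largest_slice(roi_mask(array(0L, c(3, 3, 3)), c(1, 1, 1))),
               "empty mask")
})

test_that("model inputs satisfy the channel contracts", {
  tc <- make_toy_case(24, 24, 5)
  mi <- build_input(tc$volume, tc$mask, size = 32L)
  expect_identical(dim(mi$channels), c(32L, 32L, 3L))
  expect_true(all(mi$channels >= 0 & mi$channels <= 1))
  expect_true(all(mi$channels[, , 3] %in% c(0, 1)))
  expect_equal(mi$channels[, , 2], mi$channels[, , 1] * mi$channels[, , 3])
  ## tumor occupying the full slice: crop equals the whole slice
  full <- list(volume = ct_volume(array(50, c(10, 10, 3)), c(1, 1, 1)),
               mask = roi_mask(array(1L, c(10, 10, 3)), c(1, 1, 1)))
  mif <- build_input(full$volume, full$mask, size = 16L)
  expect_equal(mean(mif$channels[, , 3]), 1)
})

test_that("disk mask foreground fraction survives crop and resize", {
  n <- 41L; r <- 9
  msk2 <- make_disk_mask(n, r)
  vol <- ct_volume(array(30, c(n, n, 3)), c(1, 1, 2.5))
  msk <- roi_mask(array(rep(msk2, 3), c(n, n, 3)), c(1, 1, 2.5))
  mi <- build_input(vol, msk, size = 64L)
  ## the square crop spans the (2r+1)-pixel bounding box plus the 25%
  ## margin on each side; the disk fills pi r^2 of it regardless of the
  ## resize resolution
  side <- 2 * ceiling((2 * r + 1) * 1.5 / 2) + 1
  expect_equal(mean(mi$channels[, , 3]), pi * r^2 / side^2, tolerance = 0.1)
})

test_that("model input is invariant to whole-voxel translations away from borders", {
  base <- array(0L, c(40, 40, 3))
  base[10:17, 12:20, 2] <- 1L
  set.seed(4)
  vox <- array(rnorm(40 * 40 * 3, 40, 15), c(40, 40, 3))
  mi1 <- build_input(ct_volume(vox, c(1, 1, 1)), roi_mask(base, c(1, 1, 1)),
                     size = 32L)
  sh <- function(a, dr, dc) {
    out <- array(0, dim(a))
    out[(1 + dr):40, (1 + dc):40, ] <- a[1:(40 - dr), 1:(40 - dc), ]
    out
  }
  mi2 <- build_input(ct_volume(sh(vox, 5, 7), c(1, 1, 1)),
                     roi_mask(sh(base, 5, 7), c(1, 1, 1)), size = 32L)
  expect_equal(mi1$channels, mi2$channels, tolerance = 1e-12)
})
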