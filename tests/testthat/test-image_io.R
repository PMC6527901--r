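test_that("NIfTI round-trip preserves values and grid", {
  run <- tiny_run(n = 4, tt = 10)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(run, path)
  back <- read_volume(path)
  expect_s3_class(back, "bold_run")
  expect_equal(back$data, run$data, tolerance = 1e-6)  # float32 storage
  expect_identical(back$grid$shape, run$grid$shape)
  expect_equal(back$grid$voxel_size_mm, run$grid$voxel_size_mm)
  expect_equal(back$tr_seconds, 2)

  # acquisition-style anisotropic voxels survive the header round-trip
  g <- volume_grid(c(5, 5, 4), c(2.75, 2.75, 4))
  vol <- array(rnorm(100), dim = c(5, 5, 4))
  p2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, p2, grid = g)
  back2 <- read_volume(p2)
  expect_equal(attr(back2, "grid")$voxel_size_mm, c(2.75, 2.75, 4),
               tolerance = 1e-6)
})

test_that("3D mask files map to brain_mask with matching voxel count", {
  set.seed(1)
  arr <- array(rbinom(64, 1, 0.5), dim = c(4, 4, 4))
  arr[1, 1, 1] <- 1
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(arr, path)
  mask <- read_volume(path, as_mask = TRUE)
  expect_s3_class(mask, "brain_mask")
  expect_equal(mask_size(mask), sum(arr))
})

test_that("reading rejects missing files and non-finite voxels", {
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
  bad <- array(1, dim = c(3, 3, 3))
  bad[2, 2, 2] <- NA
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(bad), path)
  expect_error(read_volume(path), "non-finite")
})

test_that("gaussian smoothing preserves constants and total mass", {
  vol <- array(3.7, dim = c(8, 8, 8))
  sm <- gaussian_smooth(vol, fwhm_mm = 6, grid = volume_grid(c(8, 8, 8)))
  expect_equal(sm, vol, tolerance = 1e-12)

  # reflect boundaries conserve kernel mass: spatial mean invariant
  set.seed(3)
  noisy <- array(rnorm(512), dim = c(8, 8, 8))
  sm2 <- gaussian_smooth(noisy, 6, volume_grid(c(8, 8, 8)))
  expect_equal(mean(sm2), mean(noisy), tolerance = 1e-10)
  expect_error(gaussian_smooth(noisy, -1), "fwhm")
})

test_that("impulse response matches a dense separable-convolution oracle", {
  n <- 9
  vol <- array(0, dim = c(n, n, n))
  vol[5, 5, 5] <- 1
  grid <- volume_grid(c(n, n, n), c(3, 3, 3))
  sm <- gaussian_smooth(vol, fwhm_mm = 6, grid = grid)
  sigma <- 6 / (3 * sqrt(8 * log(2)))
  r <- max(1, ceiling(4 * sigma))
  k1 <- exp(-((-r:r)^2) / (2 * sigma^2)); k1 <- k1 / sum(k1)
  # dense oracle: full triple loop over kernel taps
  oracle <- array(0, dim = c(n, n, n))
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    x <- 5 + dx; y <- 5 + dy; z <- 5 + dz
    oracle[x, y, z] <- k1[dx + r + 1] * k1[dy + r + 1] * k1[dz + r + 1]
  }
  expect_equal(sm, oracle, tolerance = 1e-12)
  expect_equal(sm[5, 5, 5], k1[r + 1]^3, tolerance = 1e-12)
})

test_that("4D smoothing never mixes time points", {
  run <- tiny_run(n = 5, tt = 4)
  sm <- gaussian_smooth(run, 6)
  for (t in 1:4) {
    expect_equal(sm$data[, , , t],
                 gaussian_smooth(run$data[, , , t], 6, run$grid),
                 tolerance = 1e-12)
  }
})

test_that("downsampling shapes, identity, and constants behave", {
  set.seed(4)
  vol <- array(rnorm(1000), dim = c(10, 10, 10))
  # independent shape computation
  expect_identical(dim(downsample(vol, 0.4)), as.integer(ceiling(0.4 * c(10, 10, 10))))
  expect_identical(dim(downsample(vol, 0.4)), c(4L, 4L, 4L))
  expect_equal(downsample(vol, 1), vol, ignore_attr = TRUE, tolerance = 1e-14)
  const <- array(2.5, dim = c(7, 7, 7))
  ds <- downsample(const, 0.55)
  expect_true(all(abs(ds - 2.5) < 1e-12))
  expect_error(downsample(vol, 0), "factor")
  expect_error(downsample(vol, 1.2), "factor")
})

test_that("mask downsampling re-binarizes at 0.5", {
  arr <- array(FALSE, c(10, 10, 10))
  arr[3:8, 3:8, 3:8] <- TRUE
  m <- brain_mask(arr)
  dm <- downsample_mask(m, 0.4)
  expect_s3_class(dm, "brain_mask")
  expect_identical(dim(dm$data), c(4L, 4L, 4L))
  expect_true(mask_size(dm) >= 1)
  expect_true(all(dm$data %in% c(TRUE, FALSE)))
})

test_that("degenerate grids and masks are rejected", {
  expect_error(volume_grid(c(0, 4, 4)), "shape")
  expect_error(volume_grid(c(4, 4, 4), c(1, -1, 1)), "voxel")
  expect_error(brain_mask(array(0, c(3, 3, 3))), "no TRUE voxels")
  expect_error(bold_run(array(1, c(2, 2, 2, 1)), 2))
})
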