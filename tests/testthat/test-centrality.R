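test_that("degree matches a brute-force correlation-matrix oracle", {
  set.seed(10)
  for (rep in 1:6) {
    tt <- sample(20:60, 1)
    M <- sample(50:200, 1)
    V <- matrix(rnorm(tt * M), tt, M)
    deg <- freqdc:::degree_from_timecourses(V, 0.2, block = 37L)
    R <- cor(V)
    diag(R) <- 0
    expect_identical(deg, as.integer(rowSums(R > 0.2)))
  }
})

test_that("hand-built four-voxel example gives degrees (1,1,0,0)", {
  # A and B share a course; C and D are exactly orthogonal to everything
  c1 <- rep(c(1, -1), 4)
  c2 <- rep(c(1, 1, -1, -1), 2)
  c3 <- c(rep(1, 4), rep(-1, 4))
  V <- cbind(c1, c1, c2, c3)
  deg <- freqdc:::degree_from_timecourses(V, 0.2)
  expect_identical(deg, c(1L, 1L, 0L, 0L))

  arr <- array(0, dim = c(4, 1, 1, 8))
  for (i in 1:4) arr[i, 1, 1, ] <- V[, i]
  run <- bold_run(arr, 2, volume_grid(c(4, 1, 1)))
  mask <- brain_mask(array(TRUE, c(4, 1, 1)), run$grid)
  dc <- degree_centrality(run, mask, 0.2)
  expect_identical(as.vector(dc$data), c(1, 1, 0, 0))
  z <- z_normalize(dc)
  expect_equal(as.vector(z$data), c(1, 1, -1, -1))  # population sd 0.5
})

test_that("identical time courses give the complete graph", {
  course <- rnorm(12)
  arr <- array(rep(course, each = 27), dim = c(3, 3, 3, 12))
  run <- bold_run(arr, 2)
  mask <- full_mask(3)
  dc <- degree_centrality(run, mask, 0.2)
  expect_true(all(dc$data[mask$data] == 26))
  expect_error(z_normalize(dc), "zero standard deviation")
})

test_that("degree is scale-invariant and monotone in the threshold", {
  run <- tiny_run(n = 4, tt = 30, seed = 21)
  mask <- full_mask(4)
  d1 <- degree_centrality(run, mask, 0.2)
  scaled <- run
  gains <- array(rep(runif(64, 0.5, 4), 30), dim = dim(run$data))
  offs <- array(rep(rnorm(64), 30), dim = dim(run$data))
  scaled$data <- run$data * gains + offs
  d2 <- degree_centrality(scaled, mask, 0.2)
  expect_identical(d1$data, d2$data)
  d_hi <- degree_centrality(run, mask, 0.5)
  expect_true(all(d_hi$data <= d1$data))
})

test_that("zero-variance voxels raise an indexed error", {
  run <- tiny_run(n = 3, tt = 10, seed = 2)
  run$data[2, 2, 2, ] <- 7
  mask <- full_mask(3)
  expect_error(degree_centrality(run, mask, 0.2), "zero-variance")
  expect_error(degree_centrality(run, mask, 1.5), "threshold_r")
})

test_that("z-maps have mask mean 0, sd 1 and are shift-invariant", {
  run <- tiny_run(n = 4, tt = 40, seed = 33)
  mask_arr <- array(FALSE, c(4, 4, 4)); mask_arr[1:3, , ] <- TRUE
  mask <- brain_mask(mask_arr)
  z <- z_normalize(degree_centrality(run, mask, 0.2))
  v <- z$data[mask$data]
  expect_lt(abs(mean(v)), 1e-10)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-10)
  expect_true(all(z$data[!mask$data] == 0))
  # adding a constant to the degrees leaves the z-map unchanged
  dc <- degree_centrality(run, mask, 0.2)
  dc2 <- dc
  dc2$data[mask$data] <- dc$data[mask$data] + 11
  expect_equal(z_normalize(dc2)$data, z$data, tolerance = 1e-12)
})

test_that("subject_band_dc composes filter, degree and z per band", {
  run <- tiny_run(n = 3, tt = 100, seed = 8)
  mask <- full_mask(3)
  sch <- build_band_scheme(0.02, 0.1, 0.04)
  maps <- subject_band_dc(run, mask, sch, 0.2)
  expect_named(maps, c("freq1", "freq2"))
  # single full band is identical to filtering once then DC
  one <- standard_scheme("full")
  m1 <- subject_band_dc(run, mask, one, 0.2)[[1]]
  direct <- z_normalize(degree_centrality(
    ideal_bandpass(run, one$bands[[1]], mask), mask, 0.2))
  expect_equal(m1$data, direct$data, tolerance = 1e-12)
  # per-band independence: reversing band order permutes the outputs
  rev_sch <- sch
  rev_sch$bands <- rev(sch$bands)
  rev_maps <- subject_band_dc(run, mask, rev_sch, 0.2)
  expect_equal(rev_maps[["freq1"]]$data, maps[["freq1"]]$data)
  expect_equal(rev_maps[["freq2"]]$data, maps[["freq2"]]$data)
})

test_that("a band-3 hub dominates its own band and no other", {
  cfg <- cohort_config(n_per_group = 3,
                       hubs = list(hub_spec(center = c(7, 7, 7),
                                            band_index = 3, coupling = 1.0,
                                            patient_attenuation = 0)),
                       seed = 7)
  masks <- cohort_masks(cfg)
  cohort <- generate_cohort(cfg)
  run <- cohort$records[[1]]$run
  reg <- nuisance_regress_run(run, masks$gm, masks$wm, masks$csf)
  reg <- gaussian_smooth(reg, cfg$smooth_fwhm_mm)
  maps <- subject_band_dc(reg, masks$gm, cfg$scheme, 0.2)
  hub <- hub_indices(cfg)
  # the map maximum in the hub's own band is a hub voxel, and the hub is
  # systematically elevated there
  expect_true(which.max(maps[["freq3"]]$data) %in% hub)
  expect_gt(median(maps[["freq3"]]$data[hub]), 1)
  # off-band maps carry no systematic hub elevation
  for (b in paste0("freq", 6:10)) {
    expect_lt(median(maps[[b]]$data[hub]), 1)
  }
})
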