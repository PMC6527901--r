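test_that("latent courses are band-limited with unit variance", {
  band <- frequency_band(0.05, 0.075)
  x <- generate_latent_course(300, 2, band, seed = 31)
  expect_length(x, 300)
  expect_equal(var(x), 1, tolerance = 1e-12)
  spec <- Mod(fft(x))^2
  keep <- freqdc:::band_bin_mask(300, 2, 0.05, 0.075)
  expect_lt(sum(spec[!keep]) / sum(spec), 1e-8)
  # too-narrow band names the minimal series length
  expect_error(generate_latent_course(40, 2, frequency_band(0.031, 0.035), 1),
               "need T >=")
})

test_that("latent courses from different seeds are uncorrelated on average", {
  # a 0.025-Hz band at T = 300 / TR = 2 holds 15 bins (~30 effective dof),
  # so single-pair |r| scatters with sd ~ 0.19; independence shows as a
  # centred distribution, not as individually tiny correlations
  band <- frequency_band(0.1, 0.125)
  rs <- vapply(1:40, function(i) {
    a <- generate_latent_course(300, 2, band, seed = 100 + i)
    b <- generate_latent_course(300, 2, band, seed = 500 + i)
    cor(a, b)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.08)       # ~2.7 SE of the mean
  expect_lt(mean(abs(rs) >= 0.5), 0.1) # no strong dependence
})

test_that("cohorts are bit-identical for the same config and seed", {
  cfg <- cohort_config(n_per_group = 3, n_volumes = 40, seed = 12)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$records[[1]]$run$data, c2$records[[1]]$run$data)
  expect_identical(c1$records[[6]]$gmv, c2$records[[6]]$gmv)
  expect_identical(lapply(c1$records, function(r) r$scores),
                   lapply(c2$records, function(r) r$scores))
  c3 <- generate_cohort(cohort_config(n_per_group = 3, n_volumes = 40,
                                      seed = 13))
  expect_false(identical(c1$records[[1]]$run$data, c3$records[[1]]$run$data))
})

test_that("cohort structure matches its configuration", {
  cfg <- cohort_config(n_per_group = 3, n_volumes = 30, seed = 2)
  co <- generate_cohort(cfg)
  expect_length(co$records, 6)
  grp <- vapply(co$records, function(r) r$group, character(1))
  expect_equal(unname(grp), rep(c("control", "patient"), each = 3))
  expect_equal(dim(co$records[[1]]$run$data), c(12, 12, 12, 30))
  expect_equal(co$records[[1]]$run$tr_seconds, 2)
  # compartments are disjoint
  expect_equal(sum(co$masks$gm$data & co$masks$wm$data), 0)
  expect_equal(sum(co$masks$gm$data & co$masks$csf$data), 0)
  expect_gt(mask_size(co$masks$wm), 0)
  # controls carry null symptom scores, patients elevated BDI
  expect_equal(co$records[[1]]$scores[["BDI"]], 0)
  expect_gt(co$records[[4]]$scores[["BDI"]], 5)
  expect_gt(co$records[[1]]$scores[["GAF"]], co$records[[4]]$scores[["GAF"]])
  # patient GMV is depressed at the atrophy site relative to controls
  at <- cfg$gmv_atrophy$center
  ctrl_g <- mean(sapply(1:3, function(i) co$records[[i]]$gmv[at[1], at[2], at[3]]))
  pat_g <- mean(sapply(4:6, function(i) co$records[[i]]$gmv[at[1], at[2], at[3]]))
  expect_gt(ctrl_g - pat_g, 0.05)
  expect_error(cohort_config(hubs = list(hub_spec(center = c(1, 1, 1)))),
               "exceeds the grid")
})

test_that("hub-pair correlations follow coupling^2/(coupling^2+1) in band", {
  # the per-subject mean hub correlation fluctuates ~0.1 through the shared
  # latent realization, so the Monte-Carlo average needs many subjects
  cfg <- cohort_config(n_per_group = 15, smooth_fwhm_mm = 0,
                       global_confound_amp = 0,
                       hubs = list(hub_spec(center = c(7, 7, 7),
                                            radius_vox = 2.5, band_index = 5,
                                            coupling = 1,
                                            patient_attenuation = 0)),
                       seed = 41)
  masks <- cohort_masks(cfg)
  plan <- freqdc:::cohort_plan(cfg)
  band5 <- cfg$scheme$bands[[5]]
  band1 <- cfg$scheme$bands[[1]]
  hub <- hub_indices(cfg)[c(1, 20, 40, 60, 81)]
  rs5 <- rs1 <- numeric(0)
  for (i in seq_len(2 * cfg$n_per_group)) {
    run <- freqdc:::generate_subject_run(cfg, i, masks, plan)
    f5 <- ideal_bandpass(run, band5, masks$gm)
    f1 <- ideal_bandpass(run, band1, masks$gm)
    V5 <- matrix(f5$data, prod(cfg$shape), cfg$n_volumes)[hub, ]
    V1 <- matrix(f1$data, prod(cfg$shape), cfg$n_volumes)[hub, ]
    R5 <- cor(t(V5)); R1 <- cor(t(V1))
    rs5 <- c(rs5, R5[upper.tri(R5)])
    rs1 <- c(rs1, R1[upper.tri(R1)])
  }
  expect_lt(abs(mean(rs5) - 0.5), 0.05)   # coupling^2/(coupling^2+1) = 1/2
  expect_lt(abs(mean(rs1)), 0.05)         # disjoint band
})

test_that("patient DC deficit at the hub is monotone in attenuation", {
  outcomes <- vapply(c(0, 0.3, 0.6), function(att) {
    cfg <- cohort_config(n_per_group = 4,
                         hubs = list(hub_spec(center = c(7, 7, 7),
                                              radius_vox = 2.5,
                                              band_index = 5,
                                              patient_attenuation = att)),
                         attenuation_spread = 0, seed = 55)
    masks <- cohort_masks(cfg)
    co <- generate_cohort(cfg)
    band5 <- cfg$scheme$bands[[5]]
    hub <- hub_indices(cfg)
    mean_hub_z <- function(rec) {
      reg <- nuisance_regress_run(rec$run, masks$gm, masks$wm, masks$csf)
      reg <- gaussian_smooth(reg, cfg$smooth_fwhm_mm)
      z <- z_normalize(degree_centrality(
        ideal_bandpass(reg, band5, masks$gm), masks$gm, 0.2))
      mean(z$data[hub])
    }
    ctrl <- mean(vapply(co$records[1:4], mean_hub_z, numeric(1)))
    pat <- mean(vapply(co$records[5:8], mean_hub_z, numeric(1)))
    ctrl - pat
  }, numeric(1))
  expect_true(all(diff(outcomes) > 0))
  expect_lt(abs(outcomes[1]), 0.5)  # no attenuation, no deficit
})

test_that("cohorts written to disk round-trip through NIfTI and TSV", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_per_group = 3, n_volumes = 20, seed = 3)
  co <- generate_cohort(cfg, out_dir = dir)
  expect_true(file.exists(file.path(dir, "subjects.tsv")))
  expect_true(file.exists(co$records[[1]]$run_path))
  run <- read_volume(co$records[[1]]$run_path)
  in_mem <- generate_cohort(cfg)
  expect_equal(run$data, in_mem$records[[1]]$run$data, tolerance = 1e-5)
  mask <- read_volume(file.path(dir, "gm_mask.nii.gz"), as_mask = TRUE)
  expect_equal(mask_size(mask), mask_size(in_mem$masks$gm))
})
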