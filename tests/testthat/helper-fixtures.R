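# Shared fixtures, built in code. Expensive cohort analyses are computed
# once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A tiny deterministic 4D run on an n^3 grid.
tiny_run <- function(n = 4, tt = 10, tr = 2, seed = 42, sd = 1) {
  set.seed(seed)
  bold_run(array(rnorm(n^3 * tt, sd = sd), dim = c(n, n, n, tt)), tr,
           volume_grid(c(n, n, n)))
}

full_mask <- function(n = 4, grid = volume_grid(c(n, n, n))) {
  brain_mask(array(TRUE, c(n, n, n)), grid)
}

# Bin-aligned tone at DFT bin k, with phase chosen orthogonal to the
# detrending basis [1, centred ramp], so it passes the detrend stage
# unchanged and isolates the band-selection property.
trend_free_tone <- function(tt, tr, k) {
  t0 <- 0:(tt - 1)
  theta <- 2 * pi * k * t0 / tt
  ramp <- t0 - mean(t0)
  a <- sum(ramp * cos(theta))
  b <- sum(ramp * sin(theta))
  phi <- atan2(a, b)  # cos(phi)*a - sin(phi)*b = 0 up to sign choice
  tone <- cos(phi) * cos(theta) - sin(phi) * sin(theta)
  stopifnot(abs(sum(ramp * tone)) < 1e-6, abs(sum(tone)) < 1e-9)
  tone
}

# Single-voxel-timecourse run over a small grid (course replicated).
tone_run <- function(course, n = 2, tr = 2) {
  tt <- length(course)
  bold_run(array(rep(course, each = n^3), dim = c(n, n, n, tt)), tr)
}

# Full per-band group analysis of the default planted-hub cohort at the
# given seed; cached because several acceptance checks share it.
planted_cohort_analysis <- function(seed = 11, n_perm = 1000) {
  cached(sprintf("planted_%d_%d", seed, n_perm), {
    cfg <- cohort_config(seed = seed)
    cohort <- generate_cohort(cfg)
    full_band <- frequency_band(0.01, 0.25, label = "full")
    maps <- cohort_dc_maps(cohort, full_band = full_band)
    groups <- split_by_group(maps, cohort$records)
    icfg <- inference_config(n_permutations = n_perm, seed = seed)
    band_labels <- vapply(cfg$scheme$bands, function(b) b$label, character(1))
    band_results <- group_by_band_tests(
      lapply(groups$control, function(m) m[band_labels]),
      lapply(groups$patient, function(m) m[band_labels]),
      cohort$masks$gm, icfg)
    full_result <- two_sample_map(
      lapply(groups$control, `[[`, "full"),
      lapply(groups$patient, `[[`, "full"),
      cohort$masks$gm, icfg)
    list(cfg = cfg, cohort = cohort, maps = maps, groups = groups,
         band_results = band_results, full_result = full_result,
         hub = hub_indices(cfg))
  })
}

# Fraction of hub voxels covered by the largest significant cluster.
hub_overlap <- function(result, hub) {
  sig <- significant_clusters(result$clusters)
  if (length(sig) == 0) return(0)
  max(vapply(sig, function(cl) length(intersect(cl$voxels, hub)), numeric(1))) /
    length(hub)
}
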