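# Seed-deterministic synthetic cohorts: 4D BOLD runs with planted
# frequency-specific hub structure, GMV maps with patient atrophy, nuisance
# compartments carrying a shared confound, and clinical score tables.

#' Specify a planted hub
#'
#' A hub is a sphere of voxels sharing one band-limited latent time course.
#' Control subjects receive the course at amplitude \code{coupling} relative
#' to the noise standard deviation *within the hub's band* (so the expected
#' band-filtered correlation between two hub voxels is
#' coupling^2 / (coupling^2 + 1)); patients receive
#' \code{coupling * (1 - patient_attenuation)}, so attenuation > 0 plants a
#' control > patient DC difference confined to the hub's band.
#'
#' The default coupling 0.73 puts control hub-pair correlations near 0.35
#' and patient ones near 0.16, straddling the r = 0.2 degree threshold —
#' the regime in which a 40% amplitude attenuation translates into a degree
#' difference.
#'
#' @param center voxel triple (1-based).
#' @param radius_vox sphere radius in voxels.
#' @param band_index index into the analysis band scheme.
#' @param coupling shared-signal amplitude relative to the in-band noise SD.
#' @param patient_attenuation nominal amplitude attenuation in patients,
#'   in [0, 1].
#' @return an object of class \code{hub_spec}.
#' @export
hub_spec <- function(center, radius_vox = 2.5, band_index = 5,
                     coupling = 0.73, patient_attenuation = 0.4) {
  stopifnot(length(center) == 3L, radius_vox > 0, coupling >= 0,
            patient_attenuation >= 0, patient_attenuation <= 1)
  structure(list(center = as.numeric(center), radius_vox = radius_vox,
                 band_index = as.integer(band_index), coupling = coupling,
                 patient_attenuation = patient_attenuation),
            class = "hub_spec")
}

#' Cohort configuration
#'
#' Defaults follow the emulated acquisition: TR = 2 s, 300 volumes, 6-mm
#' FWHM smoothing, and a 12-voxel cube at 8-mm isotropic resolution holding
#' a spherical gray-matter compartment of 552 voxels (coarse voxels keep
#' the smoothing kernel sub-voxel, so the noise field stays short-range
#' correlated relative to the small test volume). One 81-voxel hub in band 5
#' (0.1-0.125 Hz) with coupling 0.73 and 40% patient attenuation is planted
#' by default; patient BDI scores are linearly coupled to each patient's
#' attenuation draw. A shared confound course pervades gray matter and the
#' WM/CSF compartments (removed downstream by nuisance regression).
#'
#' @param shape grid shape (voxels per axis).
#' @param n_per_group subjects per group (>= 3).
#' @param tr_seconds repetition time, s.
#' @param n_volumes time points per run.
#' @param hubs list of \code{hub_spec}s.
#' @param noise_sd voxel noise standard deviation (> 0).
#' @param confound_amp amplitude of the shared physiological-confound course
#'   carried by the WM/CSF corner compartments (what nuisance regression
#'   measures and removes).
#' @param global_confound_amp amplitude at which the same confound course is
#'   additionally injected into every gray-matter voxel (default 0.5,
#'   emulating global physiological fluctuations; raise it to plant a
#'   stronger global confound for nuisance-regression testing).
#' @param gmv_atrophy list(center, radius, depth): Gaussian gray-matter
#'   volume depression applied to patients only.
#' @param attenuation_spread half-width of the per-patient uniform jitter
#'   around each hub's nominal attenuation (gives patients a severity
#'   gradient for score coupling).
#' @param score_link list(score, base, slope, noise_sd): patient score =
#'   base + slope * attenuation + noise.
#' @param smooth_fwhm_mm FWHM of the pipeline's spatial smoothing, mm.
#' @param voxel_size_mm voxel size, mm.
#' @param scheme band scheme the hub band indices refer to.
#' @param seed master seed; every draw derives from it.
#' @return an object of class \code{cohort_config}.
#' @export
cohort_config <- function(shape = c(12L, 12L, 12L), n_per_group = 24L,
                          tr_seconds = 2, n_volumes = 300L,
                          hubs = list(hub_spec(center = (shape + 2) / 2)),
                          noise_sd = 1, confound_amp = 0.5,
                          global_confound_amp = 0.5,
                          gmv_atrophy = list(center = c(5, 10, 7),
                                             radius = 1.5, depth = 0.15),
                          attenuation_spread = 0.05,
                          score_link = list(score = "BDI", base = 10,
                                            slope = 40, noise_sd = 4),
                          smooth_fwhm_mm = 6, voxel_size_mm = c(8, 8, 8),
                          scheme = standard_scheme("subbands"), seed = 1L) {
  stopifnot(n_per_group >= 3, noise_sd > 0, n_volumes >= 2, tr_seconds > 0)
  grid <- volume_grid(shape, voxel_size_mm)
  for (h in hubs) {
    if (any(h$center - h$radius_vox < 1) ||
        any(h$center + h$radius_vox > shape)) {
      stop("hub sphere exceeds the grid")
    }
    if (h$band_index < 1 || h$band_index > length(scheme$bands)) {
      stop("hub band_index outside the scheme")
    }
  }
  structure(list(shape = as.integer(shape), n_per_group = as.integer(n_per_group),
                 tr_seconds = tr_seconds, n_volumes = as.integer(n_volumes),
                 hubs = hubs, noise_sd = noise_sd, confound_amp = confound_amp,
                 global_confound_amp = global_confound_amp,
                 gmv_atrophy = gmv_atrophy,
                 attenuation_spread = attenuation_spread,
                 score_link = score_link, smooth_fwhm_mm = smooth_fwhm_mm,
                 grid = grid, scheme = scheme, seed = as.integer(seed)),
            class = "cohort_config")
}

sphere_indices <- function(shape, center, radius) {
  co <- arrayInd(seq_len(prod(shape)), shape)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
    (co[, 3] - center[3])^2
  which(d2 <= radius^2 + 1e-9)
}

#' Compartment masks of a synthetic cohort
#'
#' Gray matter is a sphere of radius \code{min(shape)/2 - 1} voxels centred
#' in the grid; the WM and CSF compartments are 3-voxel corner cubes at
#' opposite corners, outside the gray-matter sphere.
#'
#' @param cfg a \code{cohort_config}.
#' @return list of \code{brain_mask}s: \code{gm}, \code{wm}, \code{csf}.
#' @export
cohort_masks <- function(cfg) {
  shp <- cfg$shape
  ctr <- (shp + 1) / 2
  gm_arr <- array(FALSE, shp)
  gm_arr[sphere_indices(shp, ctr, min(shp) / 2 - 1)] <- TRUE
  wm_arr <- array(FALSE, shp)
  wm_arr[1:3, 1:3, 1:3] <- TRUE
  csf_arr <- array(FALSE, shp)
  csf_arr[(shp[1] - 2):shp[1], (shp[2] - 2):shp[2], (shp[3] - 2):shp[3]] <- TRUE
  wm_arr <- wm_arr & !gm_arr
  csf_arr <- csf_arr & !gm_arr
  list(gm = brain_mask(gm_arr, cfg$grid), wm = brain_mask(wm_arr, cfg$grid),
       csf = brain_mask(csf_arr, cfg$grid))
}

#' Hub voxel indices
#' @param cfg a \code{cohort_config}.
#' @param hub_index which hub (default 1).
#' @return integer vector of linear voxel indices of the hub sphere.
#' @export
hub_indices <- function(cfg, hub_index = 1L) {
  h <- cfg$hubs[[hub_index]]
  sphere_indices(cfg$shape, h$center, h$radius_vox)
}

#' Band-limited latent course
#'
#' White Gaussian noise ideal-filtered to the band and scaled to unit sample
#' variance.
#'
#' @param n_volumes number of time points.
#' @param tr repetition time, s.
#' @param band a \code{frequency_band} (must contain at least one DFT bin
#'   for this \code{n_volumes}/\code{tr}; otherwise an error states the
#'   minimal series length).
#' @param seed RNG seed.
#' @return numeric vector of length \code{n_volumes}, sample variance 1.
#' @export
generate_latent_course <- function(n_volumes, tr, band, seed) {
  x <- with_seed(seed, stats::rnorm(n_volumes))
  xf <- drop(filter_timecourses(matrix(x, ncol = 1), tr, band))
  xf / stats::sd(xf)
}

# Deterministic per-cohort draw plan: subject seeds, per-patient hub
# attenuations, and clinical scores.
cohort_plan <- function(cfg) {
  n <- cfg$n_per_group
  with_seed(cfg$seed, {
    subject_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    atts <- lapply(cfg$hubs, function(h) {
      a <- h$patient_attenuation
      lo <- max(0, a - cfg$attenuation_spread)
      hi <- min(1, a + cfg$attenuation_spread)
      stats::runif(n, lo, hi)
    })
    # severity: mean attenuation across hubs drives the linked score
    sev <- if (length(atts)) rowMeans(do.call(cbind, atts)) else numeric(n)
    link <- cfg$score_link
    linked <- link$base + link$slope * sev + stats::rnorm(n, 0, link$noise_sd)
    hamd <- pmax(0, stats::rnorm(n, 22, 7))
    gaf_p <- pmin(100, pmax(1, stats::rnorm(n, 50, 10)))
    gaf_c <- pmin(100, pmax(1, stats::rnorm(n, 90, 3)))
    epi <- pmax(1, stats::rnorm(n, 30, 12))
    dur <- pmax(0.1, stats::rnorm(n, 8, 5))
    nep <- pmax(1, round(stats::rnorm(n, 3, 1.5)))
    gmv_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n)
    list(subject_seeds = subject_seeds, gmv_seeds = gmv_seeds, atts = atts,
         linked = linked, hamd = hamd, gaf_p = gaf_p, gaf_c = gaf_c,
         epi = epi, dur = dur, nep = nep)
  })
}

# One subject's raw (unsmoothed, confounded) run. subject index i in
# 1..2n: controls first, then patients.
generate_subject_run <- function(cfg, i, masks = cohort_masks(cfg),
                                 plan = cohort_plan(cfg)) {
  n <- cfg$n_per_group
  is_patient <- i > n
  shp <- cfg$shape
  tt <- cfg$n_volumes
  sseed <- plan$subject_seeds[i]
  dat <- with_seed(sseed, {
    arr <- array(stats::rnorm(prod(shp) * tt, sd = cfg$noise_sd),
                 dim = c(shp, tt))
    flat <- matrix(arr, prod(shp), tt)
    hub_seeds <- sample.int(.Machine$integer.max - 1L,
                            length(cfg$hubs) + 1L)
    for (k in seq_along(cfg$hubs)) {
      h <- cfg$hubs[[k]]
      band <- cfg$scheme$bands[[h$band_index]]
      course <- generate_latent_course(tt, cfg$tr_seconds, band,
                                       hub_seeds[k])
      # coupling is relative to the in-band noise SD: white noise of
      # variance noise_sd^2 carries band_fraction of it inside the band
      band_frac <- sum(band_bin_mask(tt, cfg$tr_seconds,
                                     band$f_low, band$f_high)) / tt
      amp <- h$coupling * cfg$noise_sd * sqrt(band_frac)
      if (is_patient) amp <- amp * (1 - plan$atts[[k]][i - n])
      vox <- sphere_indices(shp, h$center, h$radius_vox)
      flat[vox, ] <- flat[vox, ] + amp * rep(course, each = length(vox))
    }
    if (cfg$confound_amp > 0 || cfg$global_confound_amp > 0) {
      conf <- with_seed(hub_seeds[length(hub_seeds)],
                        stats::rnorm(tt, sd = 1))
      conf <- conf / stats::sd(conf)
      nvox <- which(masks$wm$data | masks$csf$data)
      flat[nvox, ] <- flat[nvox, ] +
        cfg$confound_amp * cfg$noise_sd * rep(conf, each = length(nvox))
      if (cfg$global_confound_amp > 0) {
        gvox <- which(masks$gm$data)
        flat[gvox, ] <- flat[gvox, ] +
          cfg$global_confound_amp * cfg$noise_sd *
            rep(conf, each = length(gvox))
      }
    }
    array(flat, dim = c(shp, tt))
  })
  bold_run(dat, cfg$tr_seconds, cfg$grid)
}

# One subject's GMV map: smooth baseline plus smooth subject noise, with a
# Gaussian atrophy depression for patients.
generate_subject_gmv <- function(cfg, i, plan = cohort_plan(cfg)) {
  n <- cfg$n_per_group
  shp <- cfg$shape
  g <- with_seed(plan$gmv_seeds[i], {
    base <- array(0.6, shp) +
      gaussian_smooth(array(stats::rnorm(prod(shp), sd = 0.1), shp),
                      fwhm_mm = 8, grid = cfg$grid)
    base
  })
  if (i > n && cfg$gmv_atrophy$depth > 0) {
    at <- cfg$gmv_atrophy
    co <- arrayInd(seq_len(prod(shp)), shp)
    d2 <- (co[, 1] - at$center[1])^2 + (co[, 2] - at$center[2])^2 +
      (co[, 3] - at$center[3])^2
    dep <- at$depth * exp(-d2 / (2 * (at$radius)^2))
    g <- g - array(dep, shp)
  }
  g
}

#' Generate a synthetic cohort
#'
#' Produces one \code{subject_record} per subject (controls first, then
#' patients) carrying the subject's raw 4D run and GMV map, plus the
#' compartment masks. All draws derive from \code{cfg$seed}: the same
#' configuration and seed give a bit-identical cohort. Runs are returned
#' unsmoothed and un-regressed; the analysis pipeline applies WM/CSF
#' nuisance regression and then spatial smoothing.
#'
#' @param cfg a \code{cohort_config}.
#' @param out_dir optional directory; when given, runs, GMV maps, masks and
#'   the subject table are written as NIfTI/TSV and records carry file paths
#'   instead of arrays.
#' @return list with \code{records}, \code{masks} (gm/wm/csf), and
#'   \code{config}.
#' @export
generate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "cohort_config"))
  masks <- cohort_masks(cfg)
  plan <- cohort_plan(cfg)
  n <- cfg$n_per_group
  records <- vector("list", 2L * n)
  for (i in seq_len(2L * n)) {
    is_patient <- i > n
    id <- sprintf("%s%02d", if (is_patient) "P" else "C",
                  if (is_patient) i - n else i)
    scores <- if (is_patient) {
      j <- i - n
      sc <- c(HAMD = plan$hamd[j], GAF = plan$gaf_p[j],
              episode_weeks = plan$epi[j], duration_years = plan$dur[j],
              n_episodes = plan$nep[j])
      sc[[cfg$score_link$score]] <- plan$linked[j]
      sc
    } else {
      c(HAMD = 0, BDI = 0, GAF = plan$gaf_c[i], episode_weeks = 0,
        duration_years = 0, n_episodes = 0)
    }
    run <- generate_subject_run(cfg, i, masks, plan)
    gmv <- generate_subject_gmv(cfg, i, plan)
    if (is.null(out_dir)) {
      records[[i]] <- subject_record(id, if (is_patient) "patient" else "control",
                                     scores = scores, run = run, gmv = gmv)
    } else {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      rp <- file.path(out_dir, paste0(id, "_bold.nii.gz"))
      gp <- file.path(out_dir, paste0(id, "_gmv.nii.gz"))
      write_volume(run, rp)
      write_volume(gmv, gp, grid = cfg$grid)
      records[[i]] <- subject_record(id, if (is_patient) "patient" else "control",
                                     scores = scores, run_path = rp,
                                     gmv_path = gp)
    }
  }
  names(records) <- vapply(records, function(r) r$id, character(1))
  if (!is.null(out_dir)) {
    write_volume(masks$gm, file.path(out_dir, "gm_mask.nii.gz"))
    write_volume(masks$wm, file.path(out_dir, "wm_mask.nii.gz"))
    write_volume(masks$csf, file.path(out_dir, "csf_mask.nii.gz"))
    write_subject_table(records, file.path(out_dir, "subjects.tsv"))
  }
  list(records = records, masks = masks, config = cfg)
}
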