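# Voxel-wise group inference with nonparametric cluster-level family-wise
# error control: one-sample (sign-flip) and two-sample (label-shuffle)
# max-cluster-size permutation tests, and the per-band family of group
# contrasts.

#' Inference configuration
#'
#' @param voxel_p cluster-forming voxel-level p (default 0.001).
#' @param cluster_p cluster-level family-wise error threshold (default 0.05).
#' @param n_permutations number of permutations (>= 100).
#' @param seed integer RNG seed; identical seed + inputs give bit-identical
#'   results.
#' @param tail \code{"one_sided"} (positive direction of the contrast) or
#'   \code{"two_sided"}.
#' @return an object of class \code{inference_config}.
#' @export
inference_config <- function(voxel_p = 0.001, cluster_p = 0.05,
                             n_permutations = 1000L, seed = 1L,
                             tail = c("one_sided", "two_sided")) {
  tail <- match.arg(tail)
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_p > 0, cluster_p < 1,
            n_permutations >= 100)
  structure(list(voxel_p = voxel_p, cluster_p = cluster_p,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), tail = tail),
            class = "inference_config")
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

# M x 26 matrix of mask-local neighbour indices under 26-connectivity
# (faces + edges + corners); NA where a neighbour falls outside the mask
# or the grid. Cluster sizes depend on this connectivity choice.
mask_neighbors <- function(mask) {
  shp <- dim(mask$data)
  idx <- which(mask$data)
  M <- length(idx)
  full2loc <- integer(prod(shp))
  full2loc[idx] <- seq_len(M)
  co <- arrayInd(idx, shp)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  nbr <- matrix(NA_integer_, M, nrow(offs))
  for (k in seq_len(nrow(offs))) {
    sh <- sweep(co, 2, offs[k, ], "+")
    ok <- sh[, 1] >= 1 & sh[, 1] <= shp[1] &
      sh[, 2] >= 1 & sh[, 2] <= shp[2] &
      sh[, 3] >= 1 & sh[, 3] <= shp[3]
    lin <- rep(NA_integer_, M)
    lin[ok] <- full2loc[(sh[ok, 3] - 1L) * shp[1] * shp[2] +
                          (sh[ok, 2] - 1L) * shp[1] + sh[ok, 1]]
    lin[!is.na(lin) & lin == 0L] <- NA_integer_
    nbr[, k] <- lin
  }
  nbr
}

# Connected-component labels (26-connectivity) of a logical vector over the
# mask; returns an integer vector, 0 = below threshold.
label_components <- function(supra, nbr) {
  M <- length(supra)
  lab <- integer(M)
  cur <- 0L
  for (v in which(supra)) {
    if (lab[v] > 0L) next
    cur <- cur + 1L
    lab[v] <- cur
    stack <- v
    while (length(stack) > 0L) {
      u <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- nbr[u, ]
      nb <- nb[!is.na(nb)]
      nb <- nb[supra[nb] & lab[nb] == 0L]
      if (length(nb) > 0L) {
        lab[nb] <- cur
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

max_cluster_size <- function(supra, nbr) {
  if (!any(supra)) return(0L)
  lab <- label_components(supra, nbr)
  max(tabulate(lab))
}

# Largest cluster of a thresholded |t| map as a (size, mass) pair, ordered
# lexicographically: size first, suprathreshold mass (sum of |t| - thr)
# breaking ties. Cluster sizes on small grids are heavily discrete, which
# makes a pure size null conservative; the continuous mass tie-break makes
# the permutation p-values near-uniform while keeping size the primary
# ranking.
max_cluster_stat <- function(tvec, thr, tail, nbr) {
  best_s <- 0L
  best_m <- 0
  for (set in supra_sets(tvec, thr, tail)) {
    if (!any(set)) next
    lab <- label_components(set, nbr)
    sizes <- tabulate(lab)
    masses <- vapply(seq_along(sizes), function(ci) {
      sum(abs(tvec[lab == ci]) - thr)
    }, numeric(1))
    ord <- order(sizes, masses, decreasing = TRUE)[1]
    if (sizes[ord] > best_s ||
        (sizes[ord] == best_s && masses[ord] > best_m)) {
      best_s <- sizes[ord]
      best_m <- masses[ord]
    }
  }
  c(best_s, best_m)
}

# p-value of an observed (size, mass) cluster against the permutation null
# of lexicographic maxima (observed included in its own null).
lex_p_value <- function(size, mass, null_sizes, null_masses) {
  beats <- null_sizes > size | (null_sizes == size & null_masses >= mass)
  (1 + sum(beats)) / (length(null_sizes) + 1)
}

# Suprathreshold logical(s) for a t vector under the tail rule.
supra_sets <- function(tvec, thr, tail) {
  if (tail == "one_sided") list(pos = tvec > thr)
  else list(pos = tvec > thr, neg = tvec < -thr)
}

# Sign-flip permutation t statistics: D is n x M, S is P x n of +/-1.
# The per-voxel sum of squares is flip-invariant, so all permutation t maps
# come from one matrix product.
perm_t_one_sample <- function(D, S) {
  n <- nrow(D)
  mn <- (S %*% D) / n
  ssq <- matrix(colSums(D^2), nrow(S), ncol(D), byrow = TRUE)
  v <- (ssq / n - mn^2) * n / (n - 1)
  se <- sqrt(pmax(v, 0) / n)
  tmat <- mn / se
  tmat[!is.finite(tmat)] <- 0
  tmat
}

# Label-shuffle pooled-variance two-sample t: D is (nA+nB) x M, A is P x n
# 0/1 indicator of group-A membership per permutation.
perm_t_two_sample <- function(D, A, nA, nB) {
  n <- nA + nB
  sumA <- A %*% D
  tot <- matrix(colSums(D), nrow(A), ncol(D), byrow = TRUE)
  mA <- sumA / nA
  mB <- (tot - sumA) / nB
  ssqT <- matrix(colSums(D^2), nrow(A), ncol(D), byrow = TRUE)
  ssw <- ssqT - nA * mA^2 - nB * mB^2
  sp2 <- pmax(ssw, 0) / (n - 2)
  se <- sqrt(sp2 * (1 / nA + 1 / nB))
  tmat <- (mA - mB) / se
  tmat[!is.finite(tmat)] <- 0
  tmat
}

maps_to_matrix <- function(maps, mask) {
  idx <- which(mask$data)
  t(vapply(maps, function(m) {
    arr <- if (inherits(m, "dc_map")) m$data else as.array(m)
    arr[idx]
  }, numeric(length(idx))))
}

# Assemble the stat_map + cluster_set result shared by both tests.
# null_max is a P x 2 matrix of per-permutation (size, mass) maxima.
build_result <- function(t_obs, null_max, thr, df, contrast, mask, cfg) {
  idx <- which(mask$data)
  nbr <- mask_neighbors(mask)
  clusters <- list()
  for (set in supra_sets(t_obs, thr, cfg$tail)) {
    lab <- label_components(set, nbr)
    if (max(lab) == 0L) next
    for (ci in seq_len(max(lab))) {
      members <- which(lab == ci)
      sz <- length(members)
      mass <- sum(abs(t_obs[members]) - thr)
      p_fwe <- lex_p_value(sz, mass, null_max[, 1], null_max[, 2])
      pk <- members[which.max(abs(t_obs[members]))]
      clusters[[length(clusters) + 1L]] <- list(
        voxels = idx[members], size = sz, mass = mass,
        peak_index = idx[pk], peak_stat = t_obs[pk], cluster_p_fwe = p_fwe,
        significant = p_fwe < cfg$cluster_p)
    }
  }
  ord <- order(vapply(clusters, function(cl) -cl$size, numeric(1)))
  clusters <- clusters[ord]
  stat_arr <- array(0, dim = dim(mask$data))
  stat_arr[idx] <- t_obs
  stat <- structure(list(stat = stat_arr, df = df, contrast = contrast),
                    class = "stat_map")
  cs <- structure(list(clusters = clusters, forming_threshold = thr,
                       n_permutations = nrow(null_max), df = df,
                       contrast = contrast),
                  class = "cluster_set")
  list(stat = stat, clusters = cs)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set: %d cluster(s), forming t > %.3f, %d permutations>\n",
              length(x$clusters), x$forming_threshold, x$n_permutations))
  for (cl in x$clusters) {
    cat(sprintf("  size %d, peak t %.2f, p_fwe %.4f%s\n", cl$size,
                cl$peak_stat, cl$cluster_p_fwe,
                if (cl$significant) " *" else ""))
  }
  invisible(x)
}

#' Significant clusters of a cluster set
#' @param cs a \code{cluster_set}.
#' @return the subset of clusters with \code{cluster_p_fwe < cluster_p}.
#' @export
significant_clusters <- function(cs) {
  Filter(function(cl) isTRUE(cl$significant), cs$clusters)
}

#' One-sample cluster-level inference
#'
#' Voxel-wise one-sample t-test of the subject maps against zero
#' (df = n - 1), with clusters formed at the t quantile matching
#' \code{voxel_p} and cluster-level family-wise error assessed by sign-flip
#' permutation of subject maps (max-cluster-size null distribution, observed
#' statistic included in its own null). Zero-variance voxels get statistic 0.
#'
#' @param z_maps list of per-subject \code{dc_map}s (or 3D arrays).
#' @param mask a \code{brain_mask}.
#' @param cfg an \code{inference_config}.
#' @return list with \code{stat} (a \code{stat_map}) and \code{clusters}
#'   (a \code{cluster_set}).
#' @export
one_sample_map <- function(z_maps, mask, cfg = inference_config()) {
  n <- length(z_maps)
  if (n < 3) stop("need at least 3 subject maps")
  D <- maps_to_matrix(z_maps, mask)
  df <- n - 1
  thr <- forming_threshold(cfg, df)
  t_obs <- drop(perm_t_one_sample(D, matrix(1, 1, n)))
  nbr <- mask_neighbors(mask)
  null_max <- with_seed(cfg$seed, {
    S <- matrix(sample(c(-1, 1), cfg$n_permutations * n, replace = TRUE),
                cfg$n_permutations, n)
    tperm <- perm_t_one_sample(D, S)
    apply_max_cluster(tperm, thr, cfg$tail, nbr)
  })
  build_result(t_obs, null_max, thr, df, "mean > 0", mask, cfg)
}

forming_threshold <- function(cfg, df) {
  if (cfg$tail == "one_sided") stats::qt(1 - cfg$voxel_p, df)
  else stats::qt(1 - cfg$voxel_p / 2, df)
}

apply_max_cluster <- function(tperm, thr, tail, nbr) {
  t(vapply(seq_len(nrow(tperm)), function(p) {
    max_cluster_stat(tperm[p, ], thr, tail, nbr)
  }, numeric(2)))
}

#' Two-sample cluster-level inference
#'
#' Voxel-wise pooled-variance two-sample t-test (group A minus group B,
#' df = nA + nB - 2) with cluster-level family-wise error by group-label
#' permutation (max-cluster-size null). With \code{tail = "one_sided"} the
#' positive direction tests A > B; swap the groups for the opposite contrast.
#'
#' @param group_a,group_b lists of per-subject \code{dc_map}s (or 3D arrays).
#' @param mask a \code{brain_mask}.
#' @param cfg an \code{inference_config}.
#' @return list with \code{stat} and \code{clusters} as in
#'   \code{\link{one_sample_map}}.
#' @export
two_sample_map <- function(group_a, group_b, mask, cfg = inference_config()) {
  nA <- length(group_a)
  nB <- length(group_b)
  if (nA < 3 || nB < 3) stop("each group needs at least 3 subject maps")
  ids_a <- names(group_a)
  ids_b <- names(group_b)
  if (!is.null(ids_a) && !is.null(ids_b) &&
      length(intersect(ids_a, ids_b)) > 0) {
    stop("groups share subject ids: ",
         paste(intersect(ids_a, ids_b), collapse = ", "))
  }
  D <- rbind(maps_to_matrix(group_a, mask), maps_to_matrix(group_b, mask))
  n <- nA + nB
  df <- n - 2
  thr <- forming_threshold(cfg, df)
  obs_ind <- matrix(0, 1, n)
  obs_ind[1, seq_len(nA)] <- 1
  t_obs <- drop(perm_t_two_sample(D, obs_ind, nA, nB))
  nbr <- mask_neighbors(mask)
  null_max <- with_seed(cfg$seed, {
    A <- t(vapply(seq_len(cfg$n_permutations), function(p) {
      ind <- numeric(n)
      ind[sample.int(n, nA)] <- 1
      ind
    }, numeric(n)))
    tperm <- perm_t_two_sample(D, A, nA, nB)
    apply_max_cluster(tperm, thr, cfg$tail, nbr)
  })
  build_result(t_obs, null_max, thr, df, "group_a > group_b", mask, cfg)
}

#' Per-band group contrasts
#'
#' Runs \code{\link{two_sample_map}} within each band of a complete
#' subject-by-band table of DC maps. The group-by-band factorial question is
#' answered by this family of per-band group contrasts computed under one
#' shared configuration (same seed per band, so identical data give identical
#' results across bands).
#'
#' @param maps_a,maps_b per-group lists: one element per subject, each a
#'   named-by-band list of \code{dc_map}s (the output of
#'   \code{\link{subject_band_dc}}).
#' @param mask a \code{brain_mask}.
#' @param cfg an \code{inference_config}.
#' @return named list (by band label) of two-sample results.
#' @export
group_by_band_tests <- function(maps_a, maps_b, mask,
                                cfg = inference_config()) {
  bands <- names(maps_a[[1]])
  if (is.null(bands)) stop("subject map lists must be named by band")
  for (s in c(maps_a, maps_b)) {
    if (!identical(names(s), bands)) {
      stop("incomplete table: every subject needs the same bands")
    }
  }
  out <- lapply(bands, function(b) {
    two_sample_map(lapply(maps_a, `[[`, b), lapply(maps_b, `[[`, b),
                   mask, cfg)
  })
  names(out) <- bands
  out
}

#' Tabulate clusters
#'
#' @param results named list of inference results (per band), as returned by
#'   \code{\link{group_by_band_tests}}, or a single result.
#' @return data.frame with band, cluster id, size, peak index, peak t, p_fwe,
#'   significance flag.
#' @export
cluster_table <- function(results) {
  if (!is.null(results$clusters)) results <- list(result = results)
  rows <- list()
  for (b in names(results)) {
    cls <- results[[b]]$clusters$clusters
    for (i in seq_along(cls)) {
      cl <- cls[[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        band = b, cluster = i, size = cl$size, peak_index = cl$peak_index,
        peak_t = cl$peak_stat, p_fwe = cl$cluster_p_fwe,
        significant = cl$significant)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(band = character(), cluster = integer(),
                      size = integer(), peak_index = integer(),
                      peak_t = numeric(), p_fwe = numeric(),
                      significant = logical()))
  }
  do.call(rbind, rows)
}
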