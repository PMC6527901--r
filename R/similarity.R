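# Cross-band spatial similarity of group-averaged DC maps and Fisher r-to-z
# comparison of correlation magnitudes.

#' Pearson correlation between two maps after downsampling
#'
#' Downsamples both maps and the mask by \code{factor} (the mask re-binarized
#' at 0.5) and computes the Pearson correlation over the surviving mask
#' voxels. Downsampling to 0.4 of the resolution before correlating reduces
#' the dependence among neighbouring voxels introduced by the intrinsic
#' spatial smoothness of the maps.
#'
#' @param map_a,map_b 3D numeric arrays on the mask's grid.
#' @param mask a \code{brain_mask}.
#' @param factor resampling factor in (0, 1]; default 0.4.
#' @return list of class \code{correlation_result}: \code{r}, \code{n}
#'   (surviving voxel count), and two-sided \code{p}.
#' @export
map_correlation <- function(map_a, map_b, mask, factor = 0.4) {
  stopifnot(identical(dim(as.array(map_a)), dim(mask$data)),
            identical(dim(as.array(map_b)), dim(mask$data)))
  a <- downsample(as.array(map_a), factor, mask$grid)
  b <- downsample(as.array(map_b), factor, mask$grid)
  m <- downsample_mask(mask, factor)
  va <- a[m$data]
  vb <- b[m$data]
  n <- length(va)
  if (n < 3) stop("fewer than 3 mask voxels survive downsampling")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("zero variance over the downsampled mask")
  }
  r <- stats::cor(va, vb)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(r = r, n = n, p = p), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation r = %.4f, n = %d, p = %.3g>\n", x$r, x$n, x$p))
  invisible(x)
}

#' Compare two correlation coefficients (Fisher r-to-z)
#'
#' Treats the two correlations as independent samples:
#' z = (atanh(r_a) - atanh(r_b)) / sqrt(1/(n_a - 3) + 1/(n_b - 3)), with a
#' two-sided normal p-value and Bonferroni adjustment
#' p_adj = min(1, m * p).
#'
#' @param a,b \code{correlation_result}s (or lists with \code{r} and
#'   \code{n}); both \code{n >= 4}, both \code{|r| < 1}.
#' @param bonferroni_m positive integer Bonferroni factor.
#' @return list with \code{z} and \code{p_adj} (and unadjusted \code{p}).
#' @export
compare_correlations <- function(a, b, bonferroni_m = 1L) {
  stopifnot(a$n >= 4, b$n >= 4, bonferroni_m >= 1)
  if (abs(a$r) >= 1 || abs(b$r) >= 1) {
    stop("|r| = 1: Fisher transform diverges")
  }
  z <- (atanh(a$r) - atanh(b$r)) / sqrt(1 / (a$n - 3) + 1 / (b$n - 3))
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p = p, p_adj = min(1, bonferroni_m * p))
}

#' Similarity profile of sub-band maps against a full-band map
#'
#' Correlates the full-band group-averaged DC map with each sub-band map
#' (after downsampling), finds the band of maximum correlation, and compares
#' all band pairs with \code{\link{compare_correlations}} under a Bonferroni
#' factor of K(K-1)/2 (45 for K = 10 bands).
#'
#' @param full_map 3D array, group-averaged full-band DC map.
#' @param band_maps list of 3D arrays, group-averaged per-band DC maps.
#' @param mask a \code{brain_mask}.
#' @param factor resampling factor; default 0.4.
#' @return list with \code{correlations} (per-band
#'   \code{correlation_result}s), \code{best_band} (argmax index),
#'   \code{bonferroni_m}, and \code{pairwise} (data.frame of all band-pair
#'   comparisons with adjusted p-values).
#' @export
band_similarity_profile <- function(full_map, band_maps, mask, factor = 0.4) {
  K <- length(band_maps)
  if (K < 2) stop("need at least 2 band maps")
  cors <- lapply(band_maps, function(bm) {
    map_correlation(full_map, bm, mask, factor)
  })
  if (!is.null(names(band_maps))) names(cors) <- names(band_maps)
  rs <- vapply(cors, function(x) x$r, numeric(1))
  m <- K * (K - 1) / 2
  pairs <- utils::combn(K, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    # a perfect correlation (e.g. a band map identical to the full map)
    # has no finite Fisher z; its comparisons are reported as NA
    cmp <- if (abs(cors[[i1]]$r) >= 1 || abs(cors[[i2]]$r) >= 1) {
      list(z = NA_real_, p = NA_real_, p_adj = NA_real_)
    } else {
      compare_correlations(cors[[i1]], cors[[i2]], bonferroni_m = m)
    }
    data.frame(band_a = i1, band_b = i2, z = cmp$z, p = cmp$p,
               p_adj = cmp$p_adj)
  }))
  list(correlations = cors, best_band = which.max(rs), bonferroni_m = m,
       pairwise = pw)
}
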