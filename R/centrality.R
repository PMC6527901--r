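# Voxel-wise degree centrality: thresholded-correlation degree maps and
# z-normalization.

#' Construct a DC map
#'
#' @param data 3D numeric array; zero outside the mask.
#' @param kind \code{"raw_degree"} or \code{"z_score"}.
#' @param band_label band the map was computed in.
#' @param threshold_r correlation threshold used for binarization.
#' @param mask the \code{brain_mask} the map was computed over.
#' @return an object of class \code{dc_map}.
#' @export
dc_map <- function(data, kind = c("raw_degree", "z_score"), band_label,
                   threshold_r, mask) {
  kind <- match.arg(kind)
  stopifnot(length(dim(data)) == 3L, inherits(mask, "brain_mask"),
            identical(as.integer(dim(data)), mask$grid$shape))
  structure(list(data = data, kind = kind, band_label = band_label,
                 threshold_r = threshold_r, mask = mask),
            class = "dc_map")
}

#' @export
print.dc_map <- function(x, ...) {
  cat(sprintf("<dc_map [%s] %s, r > %g, %s>\n", x$kind, x$band_label,
              x$threshold_r, paste(dim(x$data), collapse = "x")))
  invisible(x)
}

#' In-mask values of a DC map
#' @param dc a \code{dc_map}.
#' @return numeric vector in \code{which(mask)} order.
#' @export
dc_values <- function(dc) dc$data[dc$mask$data]

#' Voxel-wise degree centrality
#'
#' For each in-mask voxel i, counts the in-mask voxels j != i whose Pearson
#' correlation with i exceeds \code{threshold_r} (strictly; negative
#' correlations never contribute). Equivalent to binarizing the full M x M
#' correlation matrix at the threshold and row-summing, but computed in
#' column blocks so the full matrix is never held in memory.
#'
#' The threshold r = 0.2 is the conventional operating point for voxel-wise
#' DC mapping.
#'
#' @param run a \code{bold_run} (typically band-filtered).
#' @param mask a \code{brain_mask} on the run's grid.
#' @param threshold_r correlation threshold in (0, 1).
#' @param block number of voxels per correlation block.
#' @return a \code{dc_map} of kind \code{"raw_degree"}.
#' @export
degree_centrality <- function(run, mask, threshold_r = 0.2, block = 2048L) {
  stopifnot(inherits(run, "bold_run"), inherits(mask, "brain_mask"))
  if (!(threshold_r > 0 && threshold_r < 1)) {
    stop("threshold_r must be in (0, 1)")
  }
  if (!grids_equal(run$grid, mask$grid)) stop("run and mask grids differ")
  V <- timecourse_matrix(run, mask)  # T x M
  deg <- degree_from_timecourses(V, threshold_r, block)
  out <- array(0, dim = dim(run$data)[1:3])
  out[mask$data] <- deg
  dc_map(out, "raw_degree", band_label = "unfiltered",
         threshold_r = threshold_r, mask = mask)
}

# Degree vector from a T x M time-course matrix.
degree_from_timecourses <- function(V, threshold_r, block = 2048L) {
  tt <- nrow(V)
  M <- ncol(V)
  if (M < 2) stop("need at least 2 masked voxels")
  mu <- colMeans(V)
  Vc <- sweep(V, 2, mu)
  ss <- sqrt(colSums(Vc^2))
  bad <- which(ss <= .Machine$double.eps * tt)
  if (length(bad) > 0) {
    stop("zero-variance time course at masked voxel index(es): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "",
         "; shrink the mask before computing degree centrality")
  }
  Z <- sweep(Vc, 2, ss, "/")       # crossprod(Z) is the correlation matrix
  deg <- integer(M)
  starts <- seq(1L, M, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, M)
    R <- crossprod(Z, Z[, s:e, drop = FALSE])  # M x (e-s+1)
    # r(i,i) = 1 > thr always: drop self
    deg[s:e] <- as.integer(colSums(R > threshold_r)) - 1L
  }
  deg
}

#' z-normalize a degree map
#'
#' Standardizes the in-mask degree values by their mean and population
#' (divide-by-M) standard deviation; out-of-mask voxels stay zero. The
#' resulting map has in-mask mean 0 and standard deviation 1.
#'
#' @param dc a \code{dc_map} of kind \code{"raw_degree"}.
#' @return a \code{dc_map} of kind \code{"z_score"}.
#' @export
z_normalize <- function(dc) {
  stopifnot(inherits(dc, "dc_map"))
  v <- dc_values(dc)
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (sd_pop <= .Machine$double.eps * max(1, abs(mu))) {
    stop("degenerate degree map: zero standard deviation over mask")
  }
  out <- array(0, dim = dim(dc$data))
  out[dc$mask$data] <- (v - mu) / sd_pop
  dc_map(out, "z_score", band_label = dc$band_label,
         threshold_r = dc$threshold_r, mask = dc$mask)
}

#' Per-band z-scored DC maps for one subject
#'
#' For each band of the scheme: ideal band-pass filter, degree centrality,
#' z-normalization. Band order is preserved.
#'
#' @param run a \code{bold_run}.
#' @param mask a \code{brain_mask}.
#' @param scheme a \code{band_scheme}.
#' @param threshold_r correlation threshold (default 0.2).
#' @return named list of \code{dc_map} (kind \code{"z_score"}), one per band.
#' @export
subject_band_dc <- function(run, mask, scheme, threshold_r = 0.2) {
  stopifnot(inherits(scheme, "band_scheme"))
  out <- lapply(scheme$bands, function(band) {
    filt <- ideal_bandpass(run, band, mask)
    dc <- degree_centrality(filt, mask, threshold_r)
    dc$band_label <- band$label
    z_normalize(dc)
  })
  names(out) <- vapply(scheme$bands, function(b) b$label, character(1))
  out
}
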