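# Voxel-wise residualization: WM/CSF nuisance regression of time courses and
# gray-matter-volume (GMV) covariate correction of DC maps.

#' Construct a covariate set
#'
#' @param values numeric matrix, one column per covariate, one row per
#'   observation (time points for nuisance regression, subjects for GMV
#'   correction).
#' @param names covariate names.
#' @param intercept whether an intercept column is added at fit time
#'   (default TRUE; residuals are then mean-free).
#' @return an object of class \code{covariate_set}.
#' @export
covariate_set <- function(values, names = colnames(values), intercept = TRUE) {
  values <- as.matrix(values)
  if (is.null(names)) names <- paste0("cov", seq_len(ncol(values)))
  colnames(values) <- names
  zero <- apply(values, 2, function(x) all(abs(x) <= .Machine$double.eps))
  if (any(zero)) {
    stop("constant-zero covariate(s): ", paste(names[zero], collapse = ", "))
  }
  structure(list(values = values, names = names, intercept = intercept),
            class = "covariate_set")
}

design_matrix <- function(cov) {
  X <- cov$values
  if (cov$intercept) X <- cbind(`(intercept)` = 1, X)
  X
}

#' Residualize a target on covariates
#'
#' Ordinary least squares of \code{target} (vector or matrix of column
#' targets) on the covariates (plus intercept when included); returns the
#' residuals, which are orthogonal to every design column.
#'
#' @param target numeric vector, or matrix with one target per column.
#' @param covariates a \code{covariate_set} or numeric matrix.
#' @return residuals, same shape as \code{target}.
#' @export
residualize <- function(target, covariates) {
  if (!inherits(covariates, "covariate_set")) {
    covariates <- covariate_set(as.matrix(covariates))
  }
  X <- design_matrix(covariates)
  y <- as.matrix(target)
  if (nrow(y) != nrow(X)) {
    stop("observation count mismatch: target ", nrow(y), ", covariates ",
         nrow(X))
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[seq(qx$rank + 1, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  res <- qr.resid(qx, y)
  if (is.vector(target)) drop(res) else res
}

#' WM/CSF nuisance regression of a BOLD run
#'
#' Extracts the mean white-matter and CSF time courses and residualizes every
#' in-mask voxel's time course against them (with intercept). Performed on
#' unsmoothed data in the standard pipeline; spatial smoothing follows.
#'
#' @param run a \code{bold_run}.
#' @param mask analysis (gray-matter) \code{brain_mask}.
#' @param wm_mask,csf_mask nuisance-compartment \code{brain_mask}s (non-empty).
#' @return a \code{bold_run} of residual time courses (0 outside the mask).
#' @export
nuisance_regress_run <- function(run, mask, wm_mask, csf_mask) {
  stopifnot(inherits(run, "bold_run"))
  for (m in list(mask, wm_mask, csf_mask)) {
    stopifnot(inherits(m, "brain_mask"))
    if (!grids_equal(run$grid, m$grid)) stop("mask grid differs from run grid")
  }
  wm <- rowMeans(timecourse_matrix(run, wm_mask))
  csf <- rowMeans(timecourse_matrix(run, csf_mask))
  covs <- covariate_set(cbind(wm = wm, csf = csf))
  V <- timecourse_matrix(run, mask)
  R <- residualize(V, covs)
  d <- dim(run$data)
  full <- matrix(0, prod(d[1:3]), d[4])
  full[which(mask$data), ] <- t(R)
  bold_run(array(full, dim = d), run$tr_seconds, run$grid)
}

#' GMV correction of DC maps
#'
#' At each in-mask voxel independently, regresses the across-subject vector
#' of DC values on the across-subject vector of gray-matter-volume values
#' (with intercept) and replaces the DC values by the residuals. The residual
#' maps are the GMV-corrected DC maps, returned in subject order. A voxel
#' whose GMV is constant across subjects keeps only the intercept (residual =
#' demeaned DC) with a warning.
#'
#' @param dc_maps list of per-subject \code{dc_map}s on a common grid.
#' @param gmv_maps list of per-subject 3D numeric arrays (same grid).
#' @param mask a \code{brain_mask}.
#' @return list of \code{dc_map}s of GMV-corrected values.
#' @export
gmv_correct_dc <- function(dc_maps, gmv_maps, mask) {
  n <- length(dc_maps)
  if (n < 3) stop("need at least 3 subjects for GMV correction")
  if (length(gmv_maps) != n) stop("dc_maps and gmv_maps lengths differ")
  idx <- which(mask$data)
  D <- t(vapply(dc_maps, function(m) m$data[idx], numeric(length(idx))))
  G <- t(vapply(gmv_maps, function(g) as.array(g)[idx], numeric(length(idx))))
  Dm <- sweep(D, 2, colMeans(D))
  Gm <- sweep(G, 2, colMeans(G))
  gvar <- colSums(Gm^2)
  const <- gvar <= .Machine$double.eps * n
  if (any(const)) {
    warning(sum(const), " voxel(s) with constant GMV across subjects; ",
            "GMV covariate dropped there (residual = demeaned DC)")
  }
  slope <- ifelse(const, 0, colSums(Dm * Gm) / pmax(gvar, .Machine$double.eps))
  Res <- Dm - sweep(Gm, 2, slope, "*")
  lapply(seq_len(n), function(i) {
    out <- array(0, dim = dim(dc_maps[[i]]$data))
    out[idx] <- Res[i, ]
    dc_map(out, "z_score", band_label = dc_maps[[i]]$band_label,
           threshold_r = dc_maps[[i]]$threshold_r, mask = mask)
  })
}
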