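# Volumetric I/O and shared image operations: grids, masks, NIfTI round-trip,
# Gaussian smoothing, and linear-interpolation downsampling.

#' Construct a volume grid
#'
#' A \code{volume_grid} records the voxel lattice geometry shared by all
#' volumes of one analysis: the number of voxels per axis, the physical voxel
#' size in millimetres, and the affine mapping 0-based voxel indices to world
#' (RAS) millimetre coordinates.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric vector of length 3, positive voxel edge
#'   lengths in mm. Default \code{c(3, 3, 3)}.
#' @param affine optional 4x4 affine matrix; defaults to a diagonal RAS
#'   affine built from \code{voxel_size_mm}.
#' @return an object of class \code{volume_grid}.
#' @export
volume_grid <- function(shape, voxel_size_mm = c(3, 3, 3), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) {
    stop("grid affine must be invertible")
  }
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid %s, voxel %s mm>\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size_mm, 4), collapse = "x")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$voxel_size_mm - b$voxel_size_mm)) < tol
}

#' Construct a 4D BOLD run
#'
#' @param data 4D numeric array (x, y, z, t); all values finite, t >= 2.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param grid a \code{volume_grid}; defaults to 3 mm isotropic voxels.
#' @return an object of class \code{bold_run}.
#' @export
bold_run <- function(data, tr_seconds, grid = NULL) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] >= 2L, tr_seconds > 0)
  if (!all(is.finite(data))) stop("BOLD data contain non-finite values")
  if (is.null(grid)) grid <- volume_grid(dim(data)[1:3])
  stopifnot(identical(as.integer(dim(data)[1:3]), grid$shape))
  structure(list(data = data, tr_seconds = as.numeric(tr_seconds),
                 grid = grid),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run %s x %d volumes, TR %g s>\n",
              paste(dim(x$data)[1:3], collapse = "x"), dim(x$data)[4],
              x$tr_seconds))
  invisible(x)
}

#' Nyquist frequency of a run
#' @param run a \code{bold_run}.
#' @return the Nyquist frequency 1/(2 TR) in Hz.
#' @export
nyquist <- function(run) 1 / (2 * run$tr_seconds)

#' Construct a brain mask
#'
#' @param data logical (or coercible) 3D array; numeric input is binarized
#'   at > 0.5. Must contain at least one TRUE voxel.
#' @param grid a \code{volume_grid}; defaults to 3 mm isotropic voxels.
#' @return an object of class \code{brain_mask}.
#' @export
brain_mask <- function(data, grid = NULL) {
  stopifnot(length(dim(data)) == 3L)
  data <- array(as.numeric(data) > 0.5, dim = dim(data))
  if (!any(data)) stop("mask contains no TRUE voxels")
  if (is.null(grid)) grid <- volume_grid(dim(data))
  stopifnot(identical(as.integer(dim(data)), grid$shape))
  structure(list(data = data, grid = grid), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask %s, %d voxels>\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' Number of in-mask voxels
#' @param mask a \code{brain_mask}.
#' @return integer count of TRUE voxels.
#' @export
mask_size <- function(mask) sum(mask$data)

grid_from_nifti <- function(img) {
  d <- dim(img)
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- RNifti::pixdim(img)
  volume_grid(d[1:3], abs(pix[1:3]), affine = RNifti::xform(img))
}

#' Read a NIfTI volume
#'
#' Reads a NIfTI-1/2 image. A 4D image is returned as a \code{bold_run}
#' (TR taken from the time-axis pixdim unless overridden); a 3D image is
#' returned as a plain numeric array with a \code{grid} attribute, or as a
#' \code{brain_mask} when \code{as_mask = TRUE} (binarized at > 0.5).
#'
#' @param path file path to a .nii or .nii.gz image.
#' @param as_mask logical; binarize a 3D image into a \code{brain_mask}.
#' @param tr_seconds optional TR override for 4D images.
#' @return \code{bold_run}, \code{brain_mask}, or 3D array.
#' @export
read_volume <- function(path, as_mask = FALSE, tr_seconds = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(vals))  # drop RNifti header attributes
  if (!all(is.finite(vals))) {
    stop("non-finite voxels in ", path)
  }
  grid <- grid_from_nifti(img)
  nd <- length(dim(vals))
  if (nd == 4L) {
    if (is.null(tr_seconds)) {
      pix <- RNifti::pixdim(img)
      tr_seconds <- if (length(pix) >= 4 && pix[4] > 0) pix[4] else 1
    }
    return(bold_run(vals, tr_seconds, grid))
  }
  if (nd != 3L) stop("expected a 3D or 4D image in ", path)
  if (as_mask) return(brain_mask(vals, grid))
  attr(vals, "grid") <- grid
  vals
}

#' Write a volume to NIfTI
#'
#' @param x a \code{bold_run}, \code{brain_mask}, or 3D/4D array (with an
#'   optional \code{grid} attribute).
#' @param path output path (.nii or .nii.gz).
#' @param grid optional \code{volume_grid} when \code{x} is a bare array.
#' @return the path, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "bold_run")) {
    grid <- x$grid
    arr <- x$data
    pd <- c(grid$voxel_size_mm, x$tr_seconds)
  } else if (inherits(x, "brain_mask")) {
    grid <- x$grid
    arr <- array(as.numeric(x$data), dim = dim(x$data))
    pd <- grid$voxel_size_mm
  } else {
    arr <- unclass(x)
    if (is.null(grid)) grid <- attr(x, "grid")
    if (is.null(grid)) grid <- volume_grid(dim(arr)[1:3])
    attr(arr, "grid") <- NULL
    pd <- grid$voxel_size_mm
    if (length(dim(arr)) == 4L) pd <- c(pd, 1)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pd
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# 1D convolution along the first array dimension with reflect boundary.
# x: matrix (n x k); kernel: odd-length numeric summing to 1.
conv1_reflect <- function(x, kernel) {
  n <- nrow(x)
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(x * kernel)
  # reflect indices: for position i (1..n) and offset o, index i+o mapped back
  idx <- seq_len(n)
  out <- matrix(0, n, ncol(x))
  for (o in seq_along(kernel)) {
    j <- idx + (o - 1L - r)
    # reflect at boundaries (mirror without repeating the edge sample twice
    # would lose constant preservation; use symmetric half-sample reflection)
    j <- ifelse(j < 1L, 1L - j, j)
    j <- ifelse(j > n, 2L * n + 1L - j, j)
    out <- out + kernel[o] * x[j, , drop = FALSE]
  }
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# Separable smoothing along the first three axes of a 3D or 4D array;
# the time axis (4th) is never touched.
smooth_spatial <- function(vol, sigmas) {
  nd <- length(dim(vol))
  for (ax in 1:3) {
    if (sigmas[ax] <= 0) next
    k <- gaussian_kernel_1d(sigmas[ax])
    perm <- c(ax, setdiff(seq_len(nd), ax))
    v <- aperm(vol, perm)
    dd <- dim(v)
    v <- conv1_reflect(matrix(v, dd[1], prod(dd[-1])), k)
    dim(v) <- dd
    vol <- aperm(v, order(perm))
  }
  vol
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with per-axis sigma (in voxels) of
#' \code{fwhm_mm / (voxel_size * sqrt(8 log 2))}. Boundaries are handled by
#' symmetric reflection, so constant volumes are preserved exactly and kernel
#' mass is conserved. 4D inputs are smoothed volume-by-volume; the time axis
#' is never smoothed.
#'
#' @param volume 3D or 4D numeric array, or a \code{bold_run}.
#' @param fwhm_mm positive full width at half maximum in mm.
#' @param grid \code{volume_grid} providing voxel sizes (taken from the run
#'   when \code{volume} is a \code{bold_run}).
#' @return same type and shape as the input.
#' @export
gaussian_smooth <- function(volume, fwhm_mm, grid = NULL) {
  if (fwhm_mm <= 0) stop("fwhm_mm must be > 0")
  if (inherits(volume, "bold_run")) {
    run <- volume
    run$data <- gaussian_smooth(run$data, fwhm_mm, run$grid)
    return(run)
  }
  if (is.null(grid)) grid <- attr(volume, "grid")
  if (is.null(grid)) grid <- volume_grid(dim(volume)[1:3])
  sigmas <- fwhm_mm / (grid$voxel_size_mm * sqrt(8 * log(2)))
  nd <- length(dim(volume))
  if (nd != 3L && nd != 4L) stop("expected a 3D or 4D array")
  smooth_spatial(volume, sigmas)
}

#' Downsample a 3D volume
#'
#' Resamples a volume to a coarser grid with per-axis output shape
#' \code{ceiling(factor * shape)}. Values are obtained by trilinear
#' interpolation at the coarse-grid sample points (voxel centres aligned by
#' the usual scale mapping \code{x_in = (i_out + 0.5)/factor_axis - 0.5},
#' clamped at the boundary), so \code{factor = 1} is the identity and a
#' constant map stays constant. Mask volumes should be re-binarized at 0.5
#' by the caller (\code{\link{downsample_mask}} does this).
#'
#' @param volume 3D numeric array.
#' @param factor real in (0, 1].
#' @param grid optional \code{volume_grid} of the input (voxel sizes of the
#'   output grid are scaled by 1/factor).
#' @return 3D array with a \code{grid} attribute for the coarse grid.
#' @export
downsample <- function(volume, factor, grid = NULL) {
  if (!(factor > 0 && factor <= 1)) stop("factor must be in (0, 1]")
  d_in <- dim(volume)
  stopifnot(length(d_in) == 3L)
  if (is.null(grid)) grid <- attr(volume, "grid")
  if (is.null(grid)) grid <- volume_grid(d_in)
  d_out <- as.integer(ceiling(factor * d_in))
  # per-axis source coordinates (0-based), clamped to [0, n-1]
  ax <- lapply(1:3, function(a) {
    scale <- d_in[a] / d_out[a]
    x <- (seq_len(d_out[a]) - 0.5) * scale - 0.5
    x <- pmin(pmax(x, 0), d_in[a] - 1)
    i0 <- pmin(floor(x), d_in[a] - 1)
    w <- x - i0
    i1 <- pmin(i0 + 1, d_in[a] - 1)
    list(i0 = as.integer(i0) + 1L, i1 = as.integer(i1) + 1L, w = w)
  })
  out <- array(0, dim = d_out)
  g <- expand.grid(x = seq_len(d_out[1]), y = seq_len(d_out[2]),
                   z = seq_len(d_out[3]))
  acc <- numeric(nrow(g))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx == 0) ax[[1]]$i0[g$x] else ax[[1]]$i1[g$x]
    iy <- if (cy == 0) ax[[2]]$i0[g$y] else ax[[2]]$i1[g$y]
    iz <- if (cz == 0) ax[[3]]$i0[g$z] else ax[[3]]$i1[g$z]
    wx <- if (cx == 0) 1 - ax[[1]]$w[g$x] else ax[[1]]$w[g$x]
    wy <- if (cy == 0) 1 - ax[[2]]$w[g$y] else ax[[2]]$w[g$y]
    wz <- if (cz == 0) 1 - ax[[3]]$w[g$z] else ax[[3]]$w[g$z]
    acc <- acc + wx * wy * wz * volume[cbind(ix, iy, iz)]
  }
  out[] <- acc
  g_out <- volume_grid(d_out, grid$voxel_size_mm * d_in / d_out)
  attr(out, "grid") <- g_out
  out
}

#' Downsample a brain mask
#'
#' Interpolates the 0/1 mask as a numeric volume and re-binarizes at > 0.5.
#'
#' @param mask a \code{brain_mask}.
#' @param factor real in (0, 1].
#' @return a \code{brain_mask} on the coarse grid.
#' @export
downsample_mask <- function(mask, factor) {
  num <- array(as.numeric(mask$data), dim = dim(mask$data))
  ds <- downsample(num, factor, mask$grid)
  brain_mask(ds > 0.5, attr(ds, "grid"))
}
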