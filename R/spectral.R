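# Frequency band schemes and ideal (rectangle-window) DFT band-pass filtering.

#' Construct a frequency band
#'
#' @param f_low lower edge in Hz (inclusive).
#' @param f_high upper edge in Hz (exclusive, except at the Nyquist
#'   frequency of the series being filtered; see \code{\link{ideal_bandpass}}).
#' @param label text label.
#' @return an object of class \code{frequency_band}.
#' @export
frequency_band <- function(f_low, f_high, label = sprintf("%g-%g Hz", f_low, f_high)) {
  stopifnot(f_low >= 0, f_high > f_low)
  structure(list(f_low = f_low, f_high = f_high, label = label),
            class = "frequency_band")
}

#' @export
print.frequency_band <- function(x, ...) {
  cat(sprintf("<band %s: [%g, %g) Hz>\n", x$label, x$f_low, x$f_high))
  invisible(x)
}

#' Build a contiguous band scheme
#'
#' Partitions \code{[f_min, f_max]} into contiguous, non-overlapping bands
#' labelled \code{freq1..freqK} in ascending order. Bands of the requested
#' width are anchored at \code{f_max}; when the width does not divide the
#' range, the lowest band absorbs the remainder. The canonical sub-band
#' analysis, \code{build_band_scheme(0.01, 0.25, 0.025)}, therefore gives
#' ten bands freq1: 0.01-0.025 Hz (0.015 Hz wide), freq2: 0.025-0.05 Hz,
#' ..., freq10: 0.225-0.25 Hz. A single band over 0.01-0.25 Hz is the
#' "full" range and one over 0.01-0.1 Hz the "conventional" range.
#'
#' @param f_min lower edge of the analysis range, Hz.
#' @param f_max upper edge of the analysis range, Hz.
#' @param width band width, Hz, in \code{(0, f_max - f_min]}.
#' @return an object of class \code{band_scheme}: list with \code{bands},
#'   \code{f_min}, \code{f_max}.
#' @export
build_band_scheme <- function(f_min, f_max, width) {
  if (f_min >= f_max) stop("f_min must be < f_max")
  if (width <= 0 || width > f_max - f_min + 1e-12) {
    stop("width must lie in (0, f_max - f_min]")
  }
  n_full <- floor((f_max - f_min) / width + 1e-9)
  rem <- (f_max - f_min) - n_full * width
  if (rem < 1e-9) {
    k <- n_full
    edges <- c(f_min, f_max - width * ((k - 1):0))
  } else {
    k <- n_full + 1L
    edges <- c(f_min, f_max - width * (n_full:0))
  }
  bands <- lapply(seq_len(k), function(i) {
    frequency_band(edges[i], edges[i + 1], label = paste0("freq", i))
  })
  structure(list(bands = bands, f_min = f_min, f_max = f_max),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat(sprintf("<band_scheme %d bands over [%g, %g] Hz>\n",
              length(x$bands), x$f_min, x$f_max))
  invisible(x)
}

#' Standard band schemes by name
#'
#' \code{"subbands"} gives the ten 0.025-Hz sub-bands over 0.01-0.25 Hz,
#' \code{"full"} the single 0.01-0.25 Hz band, and \code{"conventional"}
#' the single 0.01-0.1 Hz band.
#'
#' @param scheme one of \code{"subbands"}, \code{"full"}, \code{"conventional"}.
#' @return a \code{band_scheme}.
#' @export
standard_scheme <- function(scheme = c("subbands", "full", "conventional")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         subbands = build_band_scheme(0.01, 0.25, 0.025),
         full = build_band_scheme(0.01, 0.25, 0.24),
         conventional = build_band_scheme(0.01, 0.1, 0.09))
}

# Linear detrend + demean of the columns of a T x M matrix (OLS on [1, t]).
detrend_columns <- function(x) {
  tt <- nrow(x)
  X <- cbind(1, seq_len(tt) - (tt + 1) / 2)
  beta <- qr.coef(qr(X), x)
  x - X %*% beta
}

# Indices (1-based, into an FFT vector of length T) of bins whose frequency
# lies in [f_low, f_high); a band whose upper edge reaches Nyquist (within
# 1e-9 Hz) also keeps the Nyquist bin so a partition of [0, Nyquist]
# reconstructs the series. Conjugate-mirror bins are kept in pairs.
band_bin_mask <- function(n, tr, f_low, f_high) {
  k <- 0:(n - 1)
  kk <- pmin(k, n - k)          # conjugate-symmetric bin index
  f <- kk / (n * tr)
  nyq <- 1 / (2 * tr)
  keep <- (f >= f_low - 1e-12) & (f < f_high - 1e-12)
  if (f_high >= nyq - 1e-9) keep <- keep | (abs(f - nyq) < 1e-12)
  keep[1] <- FALSE              # DC term always removed
  keep
}

#' Ideal band-pass filtering of a BOLD run
#'
#' For each in-mask voxel: removes the temporal mean and linear trend, takes
#' the discrete Fourier transform, retains only coefficients whose bin
#' frequency f satisfies \code{f_low <= f < f_high} (conjugate-symmetric bins
#' kept in pairs; the DC term is always zeroed; a band whose upper edge
#' equals the Nyquist frequency also retains the Nyquist bin, so a contiguous
#' partition of [0, Nyquist] reconstructs the detrended input), and inverts
#' the transform. Out-of-mask voxels are set to zero. Output time courses
#' have zero mean. No zero-padding is applied: the native T-point DFT grid
#' (bin spacing 1/(T TR) Hz) defines band membership.
#'
#' Detrending and bin selection are distinct projections that do not commute
#' exactly: re-filtering an already band-limited series with
#' \code{detrend = TRUE} re-fits a (numerically tiny) trend whose in-band
#' leakage re-enters the output. Pure band selection (\code{detrend = FALSE})
#' is exactly idempotent.
#'
#' @param run a \code{bold_run}.
#' @param band a \code{frequency_band} with \code{f_high <= } Nyquist.
#' @param mask a \code{brain_mask} on the run's grid.
#' @param detrend remove the temporal mean and linear trend first
#'   (default TRUE).
#' @return a \code{bold_run} of band-limited signals.
#' @export
ideal_bandpass <- function(run, band, mask, detrend = TRUE) {
  stopifnot(inherits(run, "bold_run"), inherits(band, "frequency_band"),
            inherits(mask, "brain_mask"))
  if (!grids_equal(run$grid, mask$grid)) stop("run and mask grids differ")
  if (band$f_high > nyquist(run) + 1e-12) {
    stop(sprintf("band upper edge %g Hz exceeds Nyquist %g Hz",
                 band$f_high, nyquist(run)))
  }
  V <- timecourse_matrix(run, mask)
  Vf <- filter_timecourses(V, run$tr_seconds, band, detrend = detrend)
  d <- dim(run$data)
  full <- matrix(0, prod(d[1:3]), d[4])
  full[which(mask$data), ] <- t(Vf)
  bold_run(array(full, dim = d), run$tr_seconds, run$grid)
}

# T x M matrix of in-mask voxel time courses (column order = which(mask)).
timecourse_matrix <- function(run, mask) {
  d <- dim(run$data)
  idx <- which(mask$data)
  mat <- matrix(run$data, prod(d[1:3]), d[4])[idx, , drop = FALSE]
  t(mat)
}

# Core ideal filter on a T x M matrix of time courses.
filter_timecourses <- function(V, tr, band, detrend = TRUE) {
  n <- nrow(V)
  Vd <- if (detrend) detrend_columns(V) else V
  keep <- band_bin_mask(n, tr, band$f_low, band$f_high)
  if (!any(keep)) {
    # band too narrow for this T/tr: no DFT bin falls inside it
    min_T <- ceiling(1 / (tr * (band$f_high - band$f_low))) + 1
    stop(sprintf(
      "band [%g, %g) Hz contains no DFT bin for T = %d, TR = %g s; need T >= %d",
      band$f_low, band$f_high, n, tr, min_T))
  }
  Fz <- stats::mvfft(Vd)
  Fz[!keep, ] <- 0
  out <- stats::mvfft(Fz, inverse = TRUE) / n
  im <- max(abs(Im(out)))
  sc <- max(abs(Vd), .Machine$double.eps)  # scale by the input, not the
                                           # (possibly all-stopband) output
  if (im > 1e-8 * sc) stop("unexpected imaginary residue after inverse DFT")
  Re(out)
}
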