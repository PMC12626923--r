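# Per-subject temporal/spatial preprocessing on already-registered 4D data:
# volume discard, isotropic Gaussian smoothing, band-pass filter, linear
# detrend. Operations are linear and act only along the stated dimension(s);
# masked voxels never influence in-mask results of the temporal operations.

#' Discard initial volumes
#'
#' Drops the first `n_discard` timepoints (scanner equilibration period).
#'
#' @param series a [bold_series].
#' @param n_discard number of leading volumes to drop (`< t-length`).
#' @return a [bold_series] with `t - n_discard` volumes.
#' @export
discard_initial <- function(series, n_discard) {
  stopifnot(inherits(series, "bold_series"))
  nt <- dim(series$values)[4]
  n_discard <- as.integer(n_discard)
  if (n_discard < 0) stop("n_discard must be non-negative")
  if (n_discard >= nt)
    stop(sprintf("n_discard (%d) must be smaller than the number of volumes (%d)",
                 n_discard, nt))
  if (n_discard == 0L) return(series)
  series$values <- series$values[, , , (n_discard + 1L):nt, drop = FALSE]
  series
}

# 1D Gaussian kernel, sigma in voxels; radius covers +-3.5 sigma
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(3.5 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k / sum(k)
}

# dense n x n convolution operator with replicate (nearest-edge) padding
conv_operator <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n)   # clamp = replicate padding
    K[cbind(seq_len(n), src)] <- K[cbind(seq_len(n), src)] + k[j]
  }
  K
}

# convolve along dimension `axis` of a 3D/4D array with kernel `k`;
# implemented as a BLAS matrix product over the permuted array
convolve_axis <- function(arr, axis, k) {
  if (length(k) == 1L) return(arr)
  d <- dim(arr)
  nd <- length(d)
  K <- conv_operator(d[axis], k)
  if (axis == 1L) {
    dim(arr) <- c(d[1], prod(d[-1]))
    out <- K %*% arr
    dim(out) <- d
    return(out)
  }
  perm <- c(axis, setdiff(seq_len(nd), axis))
  a <- aperm(arr, perm)
  dim(a) <- c(d[axis], prod(d[-axis]))
  out <- K %*% a
  dim(out) <- d[perm]
  aperm(out, order(perm))
}

#' Spatial Gaussian smoothing
#'
#' Convolves each volume with a separable isotropic Gaussian of the requested
#' full width at half maximum; `sigma_vox = fwhm_mm / (voxel_size_mm * 2*sqrt(2*log(2)))`
#' per axis. Volume edges use nearest-edge (replicate) padding, which biases
#' smoothness estimates near the boundary; the in-volume sum is preserved up
#' to this boundary truncation.
#'
#' @param x a [bold_series], [voxel_map], or bare 3D/4D array.
#' @param fwhm_mm kernel FWHM in mm (`>= 0`; 0 is the identity).
#' @param voxel_size_mm voxel sizes, used only when `x` is a bare array.
#' @return same type as `x`.
#' @export
smooth_gaussian <- function(x, fwhm_mm, voxel_size_mm = c(1, 1, 1)) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0)
    stop("fwhm_mm must be a non-negative scalar")
  if (inherits(x, "bold_series") || inherits(x, "voxel_map"))
    voxel_size_mm <- x$voxel_size_mm
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  arr <- if (is.array(x) && !is.list(x)) x else x$values
  if (fwhm_mm > 0) {
    sig <- fwhm_mm / (voxel_size_mm * 2 * sqrt(2 * log(2)))
    for (ax in 1:3) arr <- convolve_axis(arr, ax, gaussian_kernel_1d(sig[ax]))
  }
  if (inherits(x, "bold_series") || inherits(x, "voxel_map")) {
    x$values <- arr
    x
  } else arr
}

# frequency vector of an N-point DFT sampled at interval tr_s (two-sided,
# in the fft's native bin order)
dft_freqs <- function(n, tr_s) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  abs(k) / (n * tr_s)
}

#' Temporal band-pass filter
#'
#' Retains spectral content with `f_low <= f <= f_high` (closed interval on
#' DFT bins) and removes everything else including the DC component, so a
#' constant series maps to zero. Default is an ideal (DFT-domain boxcar)
#' filter, matching the DFT-based definition of the downstream amplitude
#' metric; a zero-phase Butterworth magnitude response is available for
#' robustness comparisons.
#'
#' @param series a [bold_series].
#' @param band a [spectrum_band]; must lie below the series' Nyquist.
#' @param method `"ideal"` or `"butterworth"`.
#' @param order Butterworth order (per edge), default 4.
#' @return filtered [bold_series] of the same length.
#' @export
bandpass <- function(series, band = spectrum_band(), method = c("ideal", "butterworth"),
                     order = 4) {
  stopifnot(inherits(series, "bold_series"))
  method <- match.arg(method)
  check_band(band, series$tr_s)
  d <- dim(series$values)
  nt <- d[4]
  f <- dft_freqs(nt, series$tr_s)
  gain <- if (method == "ideal") {
    as.numeric(f >= band$f_low_hz & f <= band$f_high_hz)
  } else {
    hp <- 1 / sqrt(1 + (band$f_low_hz / pmax(f, 1e-12))^(2 * order))
    lp <- 1 / sqrt(1 + (f / band$f_high_hz)^(2 * order))
    g <- hp * lp
    g[f == 0] <- 0
    g
  }
  m <- matrix(series$values, ncol = nt)
  ft <- mvfft(t(m)) * gain
  m2 <- t(Re(mvfft(ft, inverse = TRUE))) / nt
  series$values <- array(m2, d)
  series
}

#' Remove per-voxel linear trend
#'
#' Subtracts the least-squares line (intercept + slope on the time index) from
#' every voxel time series; residuals have zero mean and zero covariance with
#' the time index.
#'
#' @param series a [bold_series] with `t >= 3`.
#' @return detrended [bold_series].
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "bold_series"))
  d <- dim(series$values)
  nt <- d[4]
  if (nt < 3L) stop("detrending needs at least 3 timepoints")
  m <- t(matrix(series$values, ncol = nt))   # t x V
  series$values <- array(t(detrend_cols(m)), d)
  series
}

# remove intercept+slope from each column of a t x V matrix (closed form)
detrend_cols <- function(m) {
  nt <- nrow(m)
  tt <- seq_len(nt) - (nt + 1) / 2          # centered time index
  mbar <- colMeans(m)
  slope <- crossprod(tt, m)[1, ] / sum(tt^2)
  m - outer(rep(1, nt), mbar) - outer(tt, slope)
}

#' Standard preprocessing chain
#'
#' Applies volume discard then the configured order of smoothing, band-pass
#' and detrend. The default order (smooth, bandpass, detrend) follows the
#' processing order printed in the RESTplus-style pipelines this package
#' mirrors; conventional practice detrends before filtering, selectable via
#' `order`.
#'
#' @param series a [bold_series].
#' @param n_discard leading volumes to drop (default 10).
#' @param fwhm_mm smoothing kernel FWHM in mm (default 6).
#' @param band a [spectrum_band] (default 0.01-0.08 Hz).
#' @param order character vector, a permutation of
#'   `c("smooth", "bandpass", "detrend")` (any subset allowed).
#' @param method band-pass method, see [bandpass()].
#' @return preprocessed [bold_series].
#' @export
preprocess_bold <- function(series, n_discard = 10, fwhm_mm = 6,
                            band = spectrum_band(),
                            order = c("smooth", "bandpass", "detrend"),
                            method = "ideal") {
  stopifnot(inherits(series, "bold_series"))
  if (!all(order %in% c("smooth", "bandpass", "detrend")))
    stop("order may only contain smooth, bandpass, detrend")
  series <- discard_initial(series, n_discard)
  for (step in order) {
    series <- switch(step,
                     smooth = smooth_gaussian(series, fwhm_mm),
                     bandpass = bandpass(series, band, method = method),
                     detrend = detrend_linear(series))
  }
  series
}
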