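# Static ALFF: the mean of the one-sided amplitude spectrum over the
# low-frequency band, per voxel, optionally normalized by the global
# (in-mask) mean (mALFF). A canonical fALFF (band / full-spectrum amplitude
# ratio) is provided as a clearly-labeled extension.

#' One-sided amplitude spectrum
#'
#' Scaled so that a unit-amplitude pure sinusoid at an exact DFT bin yields
#' amplitude 1 at that bin: bin `k` carries `(2/N)*|X_k|` for `0 < k < N/2`;
#' DC and (for even `N`) the Nyquist bin carry `(1/N)*|X_k|`.
#'
#' @param signal numeric vector, length >= 4, finite.
#' @param tr_s sampling interval in seconds.
#' @return list with `frequencies_hz` and `amplitudes` (length `floor(N/2)+1`).
#' @export
amplitude_spectrum <- function(signal, tr_s) {
  if (length(signal) < 4L) stop("need at least 4 samples")
  if (any(!is.finite(signal))) stop("signal contains non-finite values")
  n <- length(signal)
  half <- floor(n / 2)
  amp <- Mod(stats::fft(signal))[1:(half + 1)]
  scale <- rep(2 / n, half + 1)
  scale[1] <- 1 / n
  if (n %% 2 == 0) scale[half + 1] <- 1 / n
  list(frequencies_hz = (0:half) / (n * tr_s), amplitudes = amp * scale)
}

# indices (into the one-sided spectrum, 1-based; bin k has frequency
# (k-1)/(N*tr)) whose frequency lies in [f_low, f_high]; DC never included
band_bin_indices <- function(n, tr_s, band) {
  half <- floor(n / 2)
  f <- (0:half) / (n * tr_s)
  which(f >= band$f_low_hz & f <= band$f_high_hz & f > 0)
}

#' Static ALFF of one time series
#'
#' The amplitude spectrum is averaged over the DFT bins whose frequency lies
#' inside the closed band. `denominator = "bins"` (default) divides by the
#' number of in-band bins, the convention of the RESTplus lineage;
#' `"printed"` divides by `N2 - N1` (last minus first in-band bin index), a
#' formula-typesetting variant kept for compatibility.
#'
#' @param signal numeric time series.
#' @param tr_s sampling interval (s).
#' @param band a [spectrum_band].
#' @param denominator `"bins"` or `"printed"`.
#' @return non-negative scalar; homogeneous of degree 1 in the signal.
#' @export
alff <- function(signal, tr_s, band = spectrum_band(),
                 denominator = c("bins", "printed")) {
  denominator <- match.arg(denominator)
  check_band(band, tr_s)
  sp <- amplitude_spectrum(signal, tr_s)
  idx <- band_bin_indices(length(signal), tr_s, band)
  if (length(idx) == 0L) stop("band contains no DFT bins at this length/TR")
  s <- sum(sp$amplitudes[idx])
  den <- if (denominator == "bins") length(idx)
         else max(idx) - min(idx)
  if (den == 0) den <- 1   # single-bin band under the printed convention
  s / den
}

# amplitude spectra for all in-mask voxels at once: returns matrix
# (half+1) x V of one-sided amplitudes
spectra_matrix <- function(series) {
  nt <- dim(series$values)[4]
  m <- t(mask_matrix(series))               # t x V
  half <- floor(nt / 2)
  a <- Mod(stats::mvfft(m))[1:(half + 1), , drop = FALSE]
  scale <- rep(2 / nt, half + 1)
  scale[1] <- 1 / nt
  if (nt %% 2 == 0) scale[half + 1] <- 1 / nt
  a * scale
}

#' Voxelwise static ALFF map
#'
#' @param series a preprocessed [bold_series].
#' @param band a [spectrum_band].
#' @param denominator see [alff()].
#' @return a [voxel_map] of kind `"alff"`; out-of-mask voxels are 0.
#' @export
alff_map <- function(series, band = spectrum_band(),
                     denominator = c("bins", "printed")) {
  stopifnot(inherits(series, "bold_series"))
  denominator <- match.arg(denominator)
  if (!any(series$mask)) stop("empty mask")
  check_band(band, series$tr_s)
  nt <- dim(series$values)[4]
  idx <- band_bin_indices(nt, series$tr_s, band)
  if (length(idx) == 0L) stop("band contains no DFT bins at this length/TR")
  amps <- spectra_matrix(series)
  s <- colSums(amps[idx, , drop = FALSE])
  den <- if (denominator == "bins") length(idx) else max(max(idx) - min(idx), 1)
  vals <- array(0, dim(series$values)[1:3])
  vals[series$mask] <- s / den
  voxel_map(vals, mask = series$mask, kind = "alff",
            voxel_size_mm = series$voxel_size_mm, affine = series$affine,
            meta = list(band = unclass(band), n_band_bins = length(idx),
                        denominator = denominator, tr_s = series$tr_s,
                        subject_id = series$subject_id, session = series$session))
}

#' Normalize a map by its global (in-mask) mean
#'
#' The returned map has in-mask mean exactly 1 (mALFF). This is the
#' "divide by global mean" standardization used by RESTplus-style pipelines;
#' it makes the map invariant to global rescaling of the input series.
#'
#' @param map a [voxel_map] with positive in-mask mean.
#' @return a [voxel_map] of kind `"malff"`.
#' @export
normalize_by_global_mean <- function(map) {
  stopifnot(inherits(map, "voxel_map"))
  g <- mean(map$values[map$mask])
  if (!is.finite(g) || g <= 0) stop("global in-mask mean must be positive")
  map$values <- map$values / g
  map$values[!map$mask] <- 0
  map$kind <- "malff"
  map$meta$global_mean <- g
  map
}

#' Canonical fractional ALFF map (extension)
#'
#' Ratio of band-limited amplitude sum to the full-spectrum amplitude sum
#' (DC excluded). This is the literature's fALFF, distinct from the
#' global-mean normalization that some pipelines label "fALFF" (see
#' [normalize_by_global_mean()]).
#'
#' @inheritParams alff_map
#' @return a [voxel_map] of kind `"falff"`.
#' @export
falff_map <- function(series, band = spectrum_band()) {
  stopifnot(inherits(series, "bold_series"))
  check_band(band, series$tr_s)
  nt <- dim(series$values)[4]
  idx <- band_bin_indices(nt, series$tr_s, band)
  amps <- spectra_matrix(series)
  num <- colSums(amps[idx, , drop = FALSE])
  den <- colSums(amps[-1, , drop = FALSE])   # exclude DC
  r <- ifelse(den > 0, num / den, 0)
  vals <- array(0, dim(series$values)[1:3])
  vals[series$mask] <- r
  voxel_map(vals, mask = series$mask, kind = "falff",
            voxel_size_mm = series$voxel_size_mm, affine = series$affine,
            meta = list(band = unclass(band), tr_s = series$tr_s))
}
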