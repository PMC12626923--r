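# Dynamic ALFF: the time series is cut into sliding windows, ALFF is
# computed per window (after a per-window linear detrend by default), and
# the across-window population variance per voxel is the dALFF map, which
# is z-scored within the mask for group statistics.

#' Sliding-window scheme
#'
#' @param length_tr window length in TRs.
#' @param step_tr step between window starts in TRs (`1 <= step <= length`).
#' @return object of class `window_scheme`.
#' @export
window_scheme <- function(length_tr = 50, step_tr = 20) {
  length_tr <- as.integer(length_tr); step_tr <- as.integer(step_tr)
  if (step_tr < 1L || step_tr > length_tr)
    stop("require 1 <= step_tr <= length_tr")
  structure(list(length_tr = length_tr, step_tr = step_tr),
            class = "window_scheme")
}

#' Window start indices
#'
#' Starts are `0, S, 2S, ...` while `start + L <= n`; the trailing remainder
#' is dropped. The count is `floor((n - L)/S) + 1`.
#'
#' @param n_timepoints series length.
#' @param scheme a [window_scheme].
#' @return integer vector of 0-based start indices.
#' @export
window_starts <- function(n_timepoints, scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  n <- as.integer(n_timepoints)
  if (n < scheme$length_tr)
    stop(sprintf("series length %d shorter than window length %d",
                 n, scheme$length_tr))
  n_win <- (n - scheme$length_tr) %/% scheme$step_tr + 1L
  (seq_len(n_win) - 1L) * scheme$step_tr
}

#' Voxelwise dynamic-ALFF (across-window variance) map
#'
#' Each window is (optionally) linearly detrended, its ALFF computed at the
#' window's own frequency resolution, and the population variance (divide by
#' the number of windows m, not m-1) across windows taken per voxel.
#' Windows are rectangular (no taper), matching the sliding-window ALFF
#' lineage.
#'
#' @param series a preprocessed [bold_series].
#' @param band a [spectrum_band]; must contain at least one DFT bin at the
#'   window length.
#' @param scheme a [window_scheme].
#' @param detrend_windows detrend each window before its FFT (default TRUE;
#'   windows are short, so drift dominates otherwise).
#' @param denominator passed through to the per-window ALFF, see [alff()].
#' @return a [voxel_map] of kind `"dalff_var"` with meta `n_windows`.
#' @export
dalff_map <- function(series, band = spectrum_band(), scheme = window_scheme(),
                      detrend_windows = TRUE,
                      denominator = c("bins", "printed")) {
  stopifnot(inherits(series, "bold_series"))
  denominator <- match.arg(denominator)
  check_band(band, series$tr_s)
  nt <- dim(series$values)[4]
  starts <- window_starts(nt, scheme)
  L <- scheme$length_tr
  idx <- band_bin_indices(L, series$tr_s, band)
  if (length(idx) == 0L)
    stop("band contains no DFT bins at the window's frequency resolution")
  den <- if (denominator == "bins") length(idx) else max(max(idx) - min(idx), 1)
  scale <- rep(2 / L, floor(L / 2) + 1)
  scale[1] <- 1 / L
  if (L %% 2 == 0) scale[floor(L / 2) + 1] <- 1 / L
  sc <- scale[idx]

  m <- t(mask_matrix(series))               # t x V
  w_alff <- matrix(0, nrow = length(starts), ncol = ncol(m))
  for (w in seq_along(starts)) {
    seg <- m[(starts[w] + 1L):(starts[w] + L), , drop = FALSE]
    if (detrend_windows) seg <- detrend_cols(seg)
    a <- Mod(stats::mvfft(seg))[idx, , drop = FALSE] * sc
    w_alff[w, ] <- colSums(a) / den
  }
  nw <- nrow(w_alff)
  v <- colMeans(w_alff^2) - colMeans(w_alff)^2   # population variance
  v[v < 0] <- 0                                  # numerical guard
  vals <- array(0, dim(series$values)[1:3])
  vals[series$mask] <- v
  voxel_map(vals, mask = series$mask, kind = "dalff_var",
            voxel_size_mm = series$voxel_size_mm, affine = series$affine,
            meta = list(band = unclass(band), scheme = unclass(scheme),
                        n_windows = nw, n_band_bins = length(idx),
                        detrend_windows = detrend_windows, tr_s = series$tr_s,
                        subject_id = series$subject_id, session = series$session))
}

#' Z-score a map within its mask
#'
#' Centers and scales the in-mask values to mean 0 and population SD 1
#' (divide by n, not n-1), per subject-session map.
#'
#' @param map a [voxel_map] with non-zero in-mask SD.
#' @return a [voxel_map] of kind `"dalff_z"`.
#' @export
zscore_map <- function(map) {
  stopifnot(inherits(map, "voxel_map"))
  v <- map$values[map$mask]
  mu <- mean(v)
  sd_pop <- sqrt(mean((v - mu)^2))
  if (!is.finite(sd_pop) || sd_pop == 0)
    stop("in-mask SD is zero; cannot z-score a constant map")
  map$values[map$mask] <- (v - mu) / sd_pop
  map$values[!map$mask] <- 0
  map$kind <- "dalff_z"
  map
}
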