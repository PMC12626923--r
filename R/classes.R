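# S3 containers used throughout the pipeline: a 4D BOLD series and a 3D
# per-voxel statistic image, both carrying voxel geometry.

#' Construct a BOLD series
#'
#' A `bold_series` is a 4D lattice (x, y, z, t) of signal intensity with its
#' voxel geometry (mm), repetition time (s), an analysis mask, and identifiers.
#'
#' @param values numeric 4D array (x, y, z, t).
#' @param voxel_size_mm numeric length 1 or 3, voxel edge lengths in mm.
#' @param tr_s repetition time in seconds.
#' @param mask logical 3D array matching the spatial dims; default all TRUE.
#' @param subject_id,session identifiers (session one of "single", "pre", "post").
#' @param affine 4x4 voxel-index (0-based) to mm transform; default axis-aligned
#'   with the grid centre at the origin.
#' @return object of class `bold_series`.
#' @export
bold_series <- function(values, voxel_size_mm, tr_s, mask = NULL,
                        subject_id = "sub", session = "single", affine = NULL) {
  if (!is.array(values) || length(dim(values)) != 4L)
    stop("`values` must be a 4D array (x, y, z, t)")
  dims <- dim(values)
  if (dims[4] < 2L) stop("time dimension must have length >= 2")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (any(voxel_size_mm <= 0)) stop("voxel_size_mm must be positive")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("tr_s must be a positive scalar (seconds)")
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  if (!identical(dim(mask), dims[1:3]))
    stop("mask shape must equal the spatial dims of `values`")
  mask <- array(as.logical(mask), dims[1:3])
  if (any(!is.finite(values[rep_mask_t(mask, dims[4])])))
    stop("all in-mask values must be finite")
  if (is.null(affine)) affine <- default_affine(dims[1:3], voxel_size_mm)
  structure(list(values = values, voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 mask = mask, subject_id = subject_id, session = session,
                 affine = affine),
            class = "bold_series")
}

#' Construct a voxel map
#'
#' A `voxel_map` is a 3D per-voxel statistic image on the mask grid.
#'
#' @param values numeric 3D array.
#' @param mask logical 3D array.
#' @param kind one of "alff", "malff", "falff", "dalff_var", "dalff_z",
#'   "tstat", "zstat", "generic".
#' @param voxel_size_mm voxel edge lengths (mm), length 1 or 3.
#' @param affine 4x4 index-to-mm transform (0-based indices).
#' @param meta named list of provenance (band, parameters, ...).
#' @return object of class `voxel_map`.
#' @export
voxel_map <- function(values, mask = NULL, kind = "generic",
                      voxel_size_mm = c(1, 1, 1), affine = NULL,
                      meta = list()) {
  kinds <- c("alff", "malff", "falff", "dalff_var", "dalff_z", "tstat",
             "zstat", "generic")
  kind <- match.arg(kind, kinds)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (is.null(mask)) mask <- array(TRUE, dim(values))
  if (!identical(dim(mask), dim(values))) stop("mask shape mismatch")
  mask <- array(as.logical(mask), dim(values))
  if (any(!is.finite(values[mask])))
    stop("all in-mask values must be finite")
  if (kind %in% c("alff", "malff", "falff", "dalff_var") &&
      any(values[mask] < 0))
    stop("amplitude-type maps must be non-negative in-mask")
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  if (is.null(affine)) affine <- default_affine(dim(values), voxel_size_mm)
  values[!mask] <- 0
  structure(list(values = values, mask = mask, kind = kind,
                 voxel_size_mm = voxel_size_mm, affine = affine, meta = meta),
            class = "voxel_map")
}

#' Frequency band for spectral operations
#'
#' @param f_low_hz,f_high_hz band edges in Hz, `0 < f_low < f_high`. Validity
#'   against a series' Nyquist frequency is checked where the band is applied.
#' @return object of class `spectrum_band`.
#' @export
spectrum_band <- function(f_low_hz = 0.01, f_high_hz = 0.08) {
  if (!(is.numeric(f_low_hz) && is.numeric(f_high_hz)))
    stop("band edges must be numeric")
  if (!(0 < f_low_hz && f_low_hz < f_high_hz))
    stop("require 0 < f_low_hz < f_high_hz")
  structure(list(f_low_hz = f_low_hz, f_high_hz = f_high_hz),
            class = "spectrum_band")
}

check_band <- function(band, tr_s) {
  stopifnot(inherits(band, "spectrum_band"))
  nyq <- 1 / (2 * tr_s)
  if (band$f_high_hz >= nyq)
    stop(sprintf("band upper edge %.4f Hz is not below the Nyquist %.4f Hz",
                 band$f_high_hz, nyq))
  invisible(band)
}

# default axis-aligned affine: mm = voxel_size * (index0 - (dim-1)/2)
default_affine <- function(dims, voxel_size_mm) {
  aff <- diag(c(voxel_size_mm, 1))
  aff[1:3, 4] <- -voxel_size_mm * (dims - 1) / 2
  aff
}

# logical 4D index replicating a 3D mask across t
rep_mask_t <- function(mask, nt) {
  array(rep(mask, nt), c(dim(mask), nt))
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<bold_series> %s/%s  %dx%dx%d x %d t  TR=%.3gs  vox=%s mm  mask=%d vox\n",
              x$subject_id, x$session, d[1], d[2], d[3], d[4], x$tr_s,
              paste(signif(x$voxel_size_mm, 3), collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' @export
print.voxel_map <- function(x, ...) {
  d <- dim(x$values)
  rng <- range(x$values[x$mask])
  cat(sprintf("<voxel_map:%s> %dx%dx%d  mask=%d vox  range [%.4g, %.4g]\n",
              x$kind, d[1], d[2], d[3], sum(x$mask), rng[1], rng[2]))
  invisible(x)
}

# apply a function to the in-mask voxel-by-time matrix of a series and
# return the matrix (V x T); used by spectral ops
mask_matrix <- function(series) {
  nt <- dim(series$values)[4]
  m <- matrix(series$values, ncol = nt)[as.vector(series$mask), , drop = FALSE]
  m
}
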