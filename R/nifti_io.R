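# Minimal NIfTI-1 reader/writer (.nii and .nii.gz, single-file).
#
# No NIfTI package is assumed; this implements the fixed 348-byte NIfTI-1
# header directly. Supported on read: uint8, int16, int32, float32, float64,
# either endianness, scl_slope/scl_inter rescaling, sform or qform affines.
# Written files use little-endian float32/float64 with an sform affine and
# mm/sec units, and round-trip bit-exactly for float64.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                 `4` = list(what = "integer", size = 2, signed = TRUE),
                 `8` = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "double", size = 4, signed = TRUE),
                 `64` = list(what = "double", size = 8, signed = TRUE))

#' Write an image to NIfTI-1
#'
#' Accepts a [bold_series] (written 4D), a [voxel_map] (3D), or a bare numeric
#' array. Gzip compression is chosen from the file extension (`.nii.gz`).
#'
#' @param x object to write.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param dtype on-disk storage type; `"float64"` (default) round-trips
#'   doubles bit-exactly, `"float32"` halves file size.
#' @param voxel_size_mm,tr_s,affine geometry overrides, needed only when `x`
#'   is a bare array.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, dtype = c("float64", "float32"),
                        voxel_size_mm = c(1, 1, 1), tr_s = 1, affine = NULL) {
  dtype <- match.arg(dtype)
  if (inherits(x, "bold_series")) {
    arr <- x$values; voxel_size_mm <- x$voxel_size_mm; tr_s <- x$tr_s
    affine <- x$affine
  } else if (inherits(x, "voxel_map")) {
    arr <- x$values; voxel_size_mm <- x$voxel_size_mm; affine <- x$affine
  } else if (is.array(x)) {
    arr <- x
    voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
    if (is.null(affine))
      affine <- default_affine(dim(arr)[1:3], voxel_size_mm)
  } else stop("cannot write object of class ", paste(class(x), collapse = "/"))
  nd <- length(dim(arr))
  if (!nd %in% c(3L, 4L)) stop("only 3D or 4D images are supported")
  dt_code <- if (dtype == "float64") 64L else 16L
  bitpix <- if (dtype == "float64") 64L else 32L
  dim8 <- rep(1L, 8); dim8[1] <- nd; dim8[1 + seq_len(nd)] <- dim(arr)
  pixdim <- rep(0, 8); pixdim[1] <- 1
  pixdim[2:4] <- voxel_size_mm
  if (nd == 4L) pixdim[5] <- tr_s

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w_i8  <- function(v) writeBin(as.integer(v), con, size = 1)
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")

  w_i32(348L)                              # sizeof_hdr
  w_i8(rep(0L, 36))                        # data_type, db_name, extents, ...
  w_i16(dim8)                              # dim[8]
  w_f32(rep(0, 3))                         # intent_p1..p3
  w_i16(0L)                                # intent_code
  w_i16(dt_code); w_i16(bitpix)            # datatype, bitpix
  w_i16(0L)                                # slice_start
  w_f32(pixdim)                            # pixdim[8]
  w_f32(352)                               # vox_offset
  w_f32(1); w_f32(0)                       # scl_slope, scl_inter
  w_i16(0L); w_i8(0L)                      # slice_end, slice_code
  w_i8(10L)                                # xyzt_units = mm | sec
  w_f32(c(0, 0))                           # cal_max, cal_min
  w_f32(c(0, 0))                           # slice_duration, toffset
  w_i32(c(0L, 0L))                         # glmax, glmin
  w_i8(rep(0L, 80))                        # descrip
  w_i8(rep(0L, 24))                        # aux_file
  w_i16(0L); w_i16(2L)                     # qform_code=0, sform_code=2
  w_f32(rep(0, 6))                         # quatern_b..d, qoffset_x..z... (6 floats)
  w_f32(affine[1, ]); w_f32(affine[2, ]); w_f32(affine[3, ])
  w_i8(rep(0L, 16))                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)   # magic
  w_i8(rep(0L, 4))                         # extension flag
  sz <- if (dtype == "float64") 8L else 4L
  writeBin(as.numeric(arr), con, size = sz, endian = "little")
  invisible(path)
}

read_nifti_header <- function(con) {
  raw_hdr <- readBin(con, "raw", n = 348)
  if (length(raw_hdr) < 348) stop("malformed NIfTI header: file too short")
  rd <- function(off, what, size, n, endian, signed = TRUE)
    readBin(raw_hdr[(off + 1):(off + size * n)], what, n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rd(0, "integer", 4, 1, "little") != 348L) {
    if (rd(0, "integer", 4, 1, "big") == 348L) endian <- "big"
    else stop("malformed NIfTI header: sizeof_hdr != 348")
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("malformed NIfTI header: bad magic")
  h <- list(endian = endian,
            dim = rd(40, "integer", 2, 8, endian),
            datatype = rd(70, "integer", 2, 1, endian),
            bitpix = rd(72, "integer", 2, 1, endian),
            pixdim = rd(76, "double", 4, 8, endian),
            vox_offset = rd(108, "double", 4, 1, endian),
            scl_slope = rd(112, "double", 4, 1, endian),
            scl_inter = rd(116, "double", 4, 1, endian),
            qform_code = rd(252, "integer", 2, 1, endian),
            sform_code = rd(254, "integer", 2, 1, endian),
            quatern = rd(256, "double", 4, 3, endian),
            qoffset = rd(268, "double", 4, 3, endian),
            srow = rbind(rd(280, "double", 4, 4, endian),
                         rd(296, "double", 4, 4, endian),
                         rd(312, "double", 4, 4, endian)))
  h
}

nifti_affine <- function(h) {
  if (h$sform_code > 0) {
    rbind(h$srow, c(0, 0, 0, 1))
  } else if (h$qform_code > 0) {
    b <- h$quatern[1]; c_ <- h$quatern[2]; d <- h$quatern[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    qfac <- if (h$pixdim[1] < 0) -1 else 1
    R <- rbind(c(a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d), 2 * (b * d + a * c_)),
               c(2 * (b * c_ + a * d), a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b)),
               c(2 * (b * d - a * c_), 2 * (c_ * d + a * b), a^2 + d^2 - b^2 - c_^2))
    S <- diag(c(h$pixdim[2:3], h$pixdim[4] * qfac))
    rbind(cbind(R %*% S, h$qoffset), c(0, 0, 0, 1))
  } else {
    default_affine(pmax(h$dim[2:4], 1L), abs(h$pixdim[2:4]))
  }
}

#' Read a NIfTI-1 image
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param as `"auto"` returns a [bold_series] for 4D files and a [voxel_map]
#'   for 3D files; `"series"`/`"map"` enforce the dimensionality and raise a
#'   typed error on mismatch.
#' @param mask optional logical 3D array attached to the returned object.
#' @param kind map kind passed to [voxel_map()] for 3D reads.
#' @return a [bold_series] or [voxel_map].
#' @export
read_nifti <- function(path, as = c("auto", "series", "map"), mask = NULL,
                       kind = "generic") {
  as <- match.arg(as)
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rb")   # gzfile transparently reads plain files too
  on.exit(close(con))
  h <- read_nifti_header(con)
  nd <- h$dim[1]
  if (!nd %in% c(3L, 4L))
    stop(sprintf("unsupported NIfTI dimensionality %d (need 3D or 4D)", nd))
  dims <- h$dim[2:(1 + nd)]
  spec <- NIFTI_DT[[as.character(h$datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", h$datatype)
  # skip remaining bytes up to vox_offset (348 already consumed)
  skip <- round(h$vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = h$endian)
  if (length(vals) < n) stop("malformed NIfTI: truncated data section")
  if (h$scl_slope != 0 && !(h$scl_slope == 1 && h$scl_inter == 0))
    vals <- vals * h$scl_slope + h$scl_inter
  arr <- array(as.numeric(vals), dims)
  vox <- abs(h$pixdim[2:4]); vox[vox == 0] <- 1
  aff <- nifti_affine(h)
  if (nd == 4L) {
    if (as == "map") stop("typed mismatch: 4D file but a voxel_map was requested")
    tr <- h$pixdim[5]; if (!is.finite(tr) || tr <= 0) tr <- 1
    bold_series(arr, voxel_size_mm = vox, tr_s = tr, mask = mask,
                subject_id = sub("\\.nii(\\.gz)?$", "", basename(path)),
                affine = aff)
  } else {
    if (as == "series") stop("typed mismatch: 3D file but a bold_series was requested")
    voxel_map(arr, mask = mask, kind = kind, voxel_size_mm = vox, affine = aff)
  }
}
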