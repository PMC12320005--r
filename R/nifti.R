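# Minimal NIfTI-1 reader/writer.
#
# The package only needs single-file .nii(.gz) volumes on a shared grid, so
# this implements exactly that: NIfTI-1 header, sform affine, the common
# datatypes, optional scl_slope/scl_inter scaling, gzip transparently.
# Images written here are readable by nibabel/FSL and vice versa.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nii_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`). The affine is
#' taken from the sform when set, else the qform, else a diagonal built from
#' `pixdim`. For 4D images the repetition time is read from `pixdim[4]` and
#' must be positive.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param na_ok if `FALSE` (default), non-finite voxels are an error naming
#'   the offending voxel count (guards masks/BOLD inputs); set `TRUE` for
#'   images that legitimately carry NaN (e.g. lag maps outside the mask).
#' @return A [volume_image].
#' @export
read_volume <- function(path, na_ok = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- nii_connection(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (length(sz) == 0L) stop(sprintf("not a NIfTI-1 file: %s", path))
  if (sz != 348L) {
    sz_big <- readBin(packBits(intToBits(sz)), "integer", 1L, size = 4L,
                      endian = "big")
    if (sz_big == 348L) endian <- "big"
    else stop(sprintf("not a NIfTI-1 file (sizeof_hdr=%d): %s", sz, path))
  }
  readBin(con, "raw", 36L)                                    # unused
  dim0 <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "numeric", 3L, size = 4L, endian = endian)     # intent_p
  readBin(con, "integer", 1L, size = 2L, endian = endian)     # intent_code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)     # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)     # slice_start
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 4L)                                     # slice_end/code/units
  readBin(con, "raw", 24L)                                    # cal/slice_dur/toffset/glmax/glmin
  readBin(con, "raw", 104L)                                   # descrip + aux_file
  qform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  sform_code <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  quat <- readBin(con, "numeric", 6L, size = 4L, endian = endian)
  srow <- readBin(con, "numeric", 12L, size = 4L, endian = endian)
  readBin(con, "raw", 16L)                                    # intent_name
  magic <- readBin(con, "raw", 4L)
  magic_s <- rawToChar(magic[magic != as.raw(0)])
  if (!magic_s %in% c("n+1", "ni1"))
    stop(sprintf("not a NIfTI-1 file (bad magic '%s'): %s", magic_s, path))

  ndim <- dim0[1L]
  if (!ndim %in% c(3L, 4L))
    stop(sprintf("only 3D/4D images supported (ndim=%d): %s", ndim, path))
  dims <- dim0[2:(1L + ndim)]
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt))
    stop(sprintf("unsupported NIfTI datatype %d: %s", datatype, path))

  # skip from byte 348 to vox_offset
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) != n)
    stop(sprintf("truncated NIfTI data (%d of %d values): %s",
                 length(vals), n, path))
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter %in% c(0, NaN)))
    vals <- vals * scl_slope + ifelse(is.finite(scl_inter), scl_inter, 0)
  nbad <- sum(!is.finite(vals))
  if (nbad > 0L && !na_ok)
    stop(sprintf("%d non-finite voxel value(s) in %s (pass na_ok=TRUE if intended)",
                 nbad, path))

  if (sform_code > 0L) {
    aff <- rbind(matrix(srow, nrow = 3L, byrow = TRUE), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    aff <- quaternion_affine(quat, pixdim)
  } else {
    aff <- diag(c(abs(pixdim[2:4]), 1))
  }

  tr <- NULL
  if (ndim == 4L) {
    tr <- pixdim[5L]
    if (!is.finite(tr) || tr <= 0)
      stop(sprintf("4D image with non-positive TR (pixdim[4]=%g): %s", tr, path))
  }
  volume_image(array(vals, dim = dims), affine = aff, tr_s = tr)
}

quaternion_affine <- function(quat, pixdim) {
  b <- quat[1]; c_ <- quat[2]; d <- quat[3]
  a2 <- 1 - b * b - c_ * c_ - d * d
  a <- if (a2 > 0) sqrt(a2) else 0
  qfac <- if (is.finite(pixdim[1]) && pixdim[1] < 0) -1 else 1
  R <- matrix(c(
    a * a + b * b - c_ * c_ - d * d, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
    2 * (b * c_ + a * d), a * a + c_ * c_ - b * b - d * d, 2 * (c_ * d - a * b),
    2 * (b * d - a * c_), 2 * (c_ * d + a * b), a * a + d * d - b * b - c_ * c_
  ), nrow = 3L, byrow = TRUE)
  S <- diag(c(pixdim[2], pixdim[3], pixdim[4] * qfac))
  rbind(cbind(R %*% S, quat[4:6]), c(0, 0, 0, 1))
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file NIfTI-1 image. Data are stored as float32 by default
#' (`float64` keeps full precision, `int16`/`uint8` suit label images and
#' masks); the affine goes to the sform (code 1), and for 4D images the
#' repetition time goes to `pixdim[4]` with second time units.
#'
#' @param vol a [volume_image].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype one of `"float32"`, `"float64"`, `"int16"`, `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path,
                         datatype = c("float32", "float64", "int16", "uint8")) {
  stopifnot(is_volume(vol))
  datatype <- match.arg(datatype)
  code <- switch(datatype, float32 = 16L, float64 = 64L, int16 = 4L, uint8 = 2L)
  size <- switch(datatype, float32 = 4L, float64 = 8L, int16 = 2L, uint8 = 1L)
  dims <- dim(vol$data)
  ndim <- length(dims)
  dim0 <- rep(1L, 8L); dim0[1L] <- ndim; dim0[2:(1L + ndim)] <- dims
  vox <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  pixdim <- c(1, vox, if (ndim == 4L) vol$tr_s else 0, 0, 0, 0)

  con <- nii_connection(path, "wb")
  on.exit(close(con))
  wb <- function(x, size, what = "integer")
    writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
             con, size = size, endian = "little")
  wb(348L, 4L)
  writeBin(raw(36L), con)
  wb(dim0, 2L)
  wb(c(0, 0, 0), 4L, "numeric")         # intent_p1..3
  wb(0L, 2L)                            # intent_code
  wb(code, 2L)                          # datatype
  wb(size * 8L, 2L)                     # bitpix
  wb(0L, 2L)                            # slice_start
  wb(pixdim, 4L, "numeric")
  wb(352, 4L, "numeric")                # vox_offset
  wb(1, 4L, "numeric")                  # scl_slope
  wb(0, 4L, "numeric")                  # scl_inter
  writeBin(raw(3L), con)                # slice_end, slice_code
  writeBin(as.raw(10L), con)            # xyzt_units: mm | sec
  wb(c(0, 0, 0, 0), 4L, "numeric")      # cal_max/min, slice_duration, toffset
  wb(c(0L, 0L), 4L)                     # glmax, glmin
  writeBin(raw(104L), con)              # descrip + aux_file
  wb(0L, 2L)                            # qform_code
  wb(1L, 2L)                            # sform_code
  wb(rep(0, 6), 4L, "numeric")          # quatern b,c,d + qoffset
  wb(t(vol$affine[1:3, ]), 4L, "numeric")  # srow_x, srow_y, srow_z
  writeBin(raw(16L), con)               # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4L), con)                # extension flag
  vals <- as.numeric(vol$data)
  if (datatype %in% c("int16", "uint8")) {
    if (max(abs(vals - round(vals))) > 1e-6)
      stop("integer datatype requested for non-integer data")
    wb(round(vals), size)
  } else {
    wb(vals, size, "numeric")
  }
  invisible(path)
}
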