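# Minimal NIfTI-1 I/O.
#
# The package only needs single-file .nii / .nii.gz volumes on a regular
# grid: dim, datatype, pixdim, vox_offset, scl_slope/inter are honoured on
# read; files are written little-endian as float32 (volumes) or uint8
# (masks) with an identity orientation (sform diag(pixdim)). This is not a
# general NIfTI implementation.

NIFTI_DT <- c(uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L)

#' Write a volume or mask as NIfTI-1
#'
#' @param x a [cord_volume], [cord_mask], or 3D array (then `voxel_mm` is
#'   required).
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param voxel_mm voxel size, only used when `x` is a bare array.
#' @param datatype `"float32"` (default for volumes) or `"uint8"` (default
#'   for masks).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, voxel_mm = NULL, datatype = NULL) {
  if (inherits(x, "cord_image")) {
    grid <- x$grid
    voxel_mm <- x$voxel_mm
    if (is.null(datatype))
      datatype <- if (inherits(x, "cord_mask")) "uint8" else "float32"
  } else {
    grid <- x
    if (is.null(voxel_mm)) stop("`voxel_mm` required for bare arrays")
    voxel_mm <- as_voxel3(voxel_mm)
    if (is.null(datatype)) datatype <- "float32"
  }
  datatype <- match.arg(datatype, c("float32", "uint8", "float64"))
  d <- dim(grid)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  w_i16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w_f32 <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                   # sizeof_hdr
  w_raw(28L)                                    # data_type, db_name
  w_i32(0L); w_i16(0L)                          # extents, session_error
  writeBin(charToRaw("r"), con); w_raw(1L)      # regular, dim_info
  w_i16(c(3L, d, 1L, 1L, 1L, 1L))               # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)                  # intent_p*, intent_code
  w_i16(NIFTI_DT[[datatype]])
  w_i16(switch(datatype, uint8 = 8L, float32 = 32L, float64 = 64L))
  w_i16(0L)                                     # slice_start
  w_f32(c(1, voxel_mm, 1, 1, 1, 1))             # pixdim (qfac first)
  w_f32(352)                                    # vox_offset
  w_f32(1); w_f32(0)                            # scl_slope, scl_inter
  w_i16(0L)                                     # slice_end
  writeBin(as.raw(c(0L, 2L)), con)              # slice_code, xyzt_units = mm
  w_f32(c(0, 0, 0, 0))                          # cal_max/min, slice_duration, toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  w_raw(80L + 24L)                              # descrip, aux_file
  w_i16(c(0L, 1L))                              # qform_code, sform_code
  w_f32(c(0, 0, 0, 0, 0, 0))                    # quatern, qoffset
  w_f32(c(voxel_mm[1L], 0, 0, 0))               # srow_x
  w_f32(c(0, voxel_mm[2L], 0, 0))               # srow_y
  w_f32(c(0, 0, voxel_mm[3L], 0))               # srow_z
  w_raw(16L)                                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)   # magic
  w_raw(4L)                                     # extension flag -> offset 352

  vals <- as.vector(grid)
  if (datatype == "uint8") {
    writeBin(as.raw(as.integer(vals != 0)), con)
  } else {
    writeBin(as.numeric(vals), con,
             size = if (datatype == "float32") 4L else 8L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return A [cord_volume] (use [load_external_mask()] for masks).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, raw(), 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  rd <- function(what, n, size, off, endian) {
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size, endian = endian)
  }
  endian <- "little"
  if (rd(integer(), 1L, 4L, 0L, endian) != 348L) {
    endian <- "big"
    if (rd(integer(), 1L, 4L, 0L, endian) != 348L)
      stop("not a NIfTI-1 file: ", path)
  }
  dims <- rd(integer(), 8L, 2L, 40L, endian)
  ndim <- dims[1L]
  if (ndim < 3L) stop("expected a 3D NIfTI image")
  d <- dims[2:4]
  if (ndim > 3L && any(dims[5:(1L + ndim)] > 1L))
    stop("4D+ NIfTI images are not supported")
  datatype <- rd(integer(), 1L, 2L, 70L, endian)
  pixdim <- rd(numeric(), 8L, 4L, 76L, endian)
  vox_offset <- rd(numeric(), 1L, 4L, 108L, endian)
  scl_slope <- rd(numeric(), 1L, 4L, 112L, endian)
  scl_inter <- rd(numeric(), 1L, 4L, 116L, endian)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, raw(), skip)
  nvox <- prod(d)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, integer(), nvox, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, integer(), nvox, size = 2L, endian = endian)),
    "8"  = as.numeric(readBin(con, integer(), nvox, size = 4L, endian = endian)),
    "16" = readBin(con, numeric(), nvox, size = 4L, endian = endian),
    "64" = readBin(con, numeric(), nvox, size = 8L, endian = endian),
    stop("unsupported NIfTI datatype code ", datatype))
  if (length(vals) != nvox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  cord_volume(array(vals, dim = d), voxel_mm = pixdim[2:4])
}
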