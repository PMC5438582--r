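## Minimal NIfTI-1 I/O.
##
## No NIfTI package ships with the supported tool stack, so the package
## carries its own single-file (.nii / .nii.gz) reader and writer covering
## the subset this pipeline needs: 3D volumes, scalar datatypes, pixdim
## voxel spacing, scl_slope/scl_inter rescaling. qform/sform rotations are
## ignored; the on-disk axis order is taken literally (x fastest), and the
## third on-disk axis is treated as cranio-caudal.

NIFTI_DATATYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`), applying the
#' header's `scl_slope`/`scl_inter` rescaling. Only 3D scalar images are
#' supported; both endiannesses are handled.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (3D array, on-disk x/y/z order) and
#'   `spacing` (numeric length 3, mm, from `pixdim`).
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path)
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported")
  rd_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2L * n)],
    "integer", n = n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4L * n)],
    "double", n = n, size = 4L, endian = endian)
  dim0 <- rd_i16(40L, 8L)
  ndim <- dim0[1]
  if (ndim < 3L) stop("expected a 3D NIfTI volume, got ", ndim, "D")
  dims <- dim0[2:(ndim + 1L)]
  if (ndim > 3L && any(dims[4:ndim] > 1L))
    stop("only 3D NIfTI volumes are supported")
  dims <- dims[1:3]
  datatype <- rd_i16(70L, 1L)
  spec <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd_f32(76L, 8L)
  spacing <- abs(pixdim[2:4])
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or non-positive voxel spacing in NIfTI header of ", path)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI pixel data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims), spacing = spacing)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3D array as a single-file little-endian NIfTI-1 image with
#' float64 data (so HU round-trips are exact), identity-scaled
#' (`scl_slope = 1`), diagonal sform.
#'
#' @param data 3D numeric array in on-disk x/y/z order.
#' @param spacing Numeric length 3, voxel spacing in mm.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @keywords internal
write_nifti <- function(data, spacing, path) {
  stopifnot(length(dim(data)) == 3L, length(spacing) == 3L,
            all(spacing > 0))
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L,
                                endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L,
                                endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L,
                                endian = "little")
  w_pad <- function(n) writeBin(raw(n), con)
  w_i32(348L)                      # sizeof_hdr
  w_pad(35L)                       # data_type, db_name, extents, ...
  writeBin(as.raw(0L), con)        # dim_info
  w_i16(c(3L, dim(data), 1L, 1L, 1L, 1L))   # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)     # intent_p*, intent_code
  w_i16(64L); w_i16(64L)           # datatype float64, bitpix
  w_i16(0L)                        # slice_start
  w_f32(c(1, spacing, 0, 0, 0, 0)) # pixdim (qfac = 1)
  w_f32(352)                       # vox_offset
  w_f32(1); w_f32(0)               # scl_slope, scl_inter
  w_i16(0L); writeBin(raw(2L), con)        # slice_end, slice_code, xyzt
  w_f32(c(0, 0, 0, 0))             # cal_max, cal_min, slice_dur, toffset
  w_i32(c(0L, 0L))                 # glmax, glmin
  desc <- charToRaw("ctcomp")
  writeBin(c(desc, raw(80L - length(desc))), con)  # descrip
  w_pad(24L)                       # aux_file
  w_i16(c(0L, 1L))                 # qform_code 0, sform_code 1
  w_f32(c(0, 0, 0, 0, 0, 0))       # quatern, qoffset
  w_f32(c(spacing[1], 0, 0, 0))    # srow_x
  w_f32(c(0, spacing[2], 0, 0))    # srow_y
  w_f32(c(0, 0, spacing[3], 0))    # srow_z
  w_pad(16L)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)      # magic
  writeBin(raw(4L), con)           # extension flag
  writeBin(as.double(as.vector(data)), con, size = 8L, endian = "little")
  invisible(path)
}
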