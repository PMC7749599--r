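# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package ships with the supported toolchain, so the subset of the
# format this package needs is implemented here: 3-D or 4-D volumes, identity
# affine (sform code 1), float32/float64/int volumes, sequential read of
# gzipped files. Headers are fixed at 348 bytes with vox_offset 352.

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D or 4-D array as a NIfTI-1 volume
#'
#' Writes a single-file NIfTI-1 image with unit voxel size and identity
#' orientation (sform code 1). Integer arrays are stored as int32, numeric
#' arrays as float32. A `.gz` suffix triggers gzip compression.
#'
#' @param x 3-D or 4-D array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  if (!(length(dim(x)) %in% c(3L, 4L))) {
    stopf("write_nifti: x must be a 3-D or 4-D array")
  }
  dims <- dim(x)
  ndim <- length(dims)
  datatype <- if (is.integer(x)) 8L else 16L
  bitpix <- 32L

  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L, 4)                      # sizeof_hdr
  wraw(35)                         # data_type, db_name, extents, ...
  writeBin(as.raw(0L), con)        # dim_info
  wi(c(ndim, dims, rep(1L, 7L - ndim)), 2)  # dim[8]
  wf(c(0, 0, 0))                   # intent_p1..p3
  wi(0L, 2)                        # intent_code
  wi(datatype, 2)                  # datatype
  wi(bitpix, 2)                    # bitpix
  wi(0L, 2)                        # slice_start
  wf(c(1, rep(1, 7)))              # pixdim (qfac = 1, unit voxels)
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0L, 2)                        # slice_end
  writeBin(as.raw(c(0L, 10L)), con) # slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                 # glmax, glmin
  desc <- charToRaw("cpcmorph")
  writeBin(c(desc, raw(80 - length(desc))), con)  # descrip
  wraw(24)                         # aux_file
  wi(0L, 2); wi(1L, 2)             # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))   # quatern, qoffset
  wf(c(1, 0, 0, 0)); wf(c(0, 1, 0, 0)); wf(c(0, 0, 1, 0))  # srow identity
  wraw(16)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  wraw(4)                          # extension flag
  if (datatype == 8L) {
    writeBin(as.integer(x), con, size = 4L, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Sequential reader for single-file NIfTI-1 images (gzip transparently
#' handled), supporting the common scalar datatypes and `scl_slope` /
#' `scl_inter` rescaling. Only the voxel data and grid shape are interpreted;
#' orientation metadata are ignored (inputs are assumed co-registered).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return Array of dimension `dim[1:ndim]` with attribute `pixdim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("read_nifti: no such file: %s", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stopf("read_nifti: truncated header in %s", path)

  rd <- function(off, what, n, size, signed = TRUE, endian) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, endian = endian) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian = endian) != 348L) {
      stopf("read_nifti: %s is not a NIfTI-1 file", path)
    }
  }
  dims_raw <- rd(40L, "integer", 8L, 2L, endian = endian)
  ndim <- dims_raw[1L]
  if (ndim < 3L || ndim > 4L) stopf("read_nifti: unsupported dimensionality %d", ndim)
  dims <- dims_raw[2L:(1L + ndim)]
  datatype <- rd(70L, "integer", 1L, 2L, endian = endian)
  pixdim <- rd(76L, "numeric", 8L, 4L, endian = endian)
  vox_offset <- rd(108L, "numeric", 1L, 4L, endian = endian)
  scl_slope <- rd(112L, "numeric", 1L, 4L, endian = endian)
  scl_inter <- rd(116L, "numeric", 1L, 4L, endian = endian)

  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stopf("read_nifti: unsupported datatype code %d", datatype)
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stopf("read_nifti: truncated data in %s", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  out <- array(vals, dim = dims)
  attr(out, "pixdim") <- pixdim[2L:(1L + ndim)]
  out
}
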