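# Minimal NIfTI-1 single-file (.nii / .nii.gz) label-volume I/O.  No NIfTI
# reader is available in the installed R stack, so the 348-byte header is
# read and written directly.  Only what label volumes need is supported:
# 3D dims, integer/float datatypes, pixdim spacing in mm.

.NIFTI_DT <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),   # uint8
  `4` = list(what = "integer", size = 2L, signed = TRUE),    # int16
  `8` = list(what = "integer", size = 4L, signed = TRUE),    # int32
  `16` = list(what = "double", size = 4L, signed = TRUE),    # float32
  `64` = list(what = "double", size = 8L, signed = TRUE)     # float64
)

.niftiConnection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Minimal reader for single-file NIfTI-1 (\code{.nii} or \code{.nii.gz})
#' volumes as written by [writeNifti()] or standard tools.  Returns the data
#' array and voxel spacing.
#'
#' @param path file path.
#' @return List with \code{data} (3D array) and \code{pixdim} (numeric
#'   length-3, mm).
#' @export
readNifti <- function(path) {
  con <- .niftiConnection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(hdr[(off + 1L):length(hdr)], what, n = n, size = size,
            signed = signed, endian = "little")
  sizeof <- rd(0L, "integer", 1L, 4L)
  if (sizeof != 348L) stop(path, " is not little-endian NIfTI-1")
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop(path, " lacks NIfTI magic")
  dim0 <- rd(40L, "integer", 8L, 2L)
  ndim <- dim0[1]
  if (ndim < 3L) stop("expected a 3D volume in ", path)
  dims <- dim0[2:(1 + ndim)]
  if (ndim > 3L && any(dims[4:length(dims)] != 1L))
    stop("only 3D volumes are supported")
  dims <- dims[1:3]
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- .NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype)
  pixdim <- rd(76L, "double", 8L, 4L)[2:4]
  voxOffset <- rd(108L, "double", 1L, 4L)
  skip <- as.integer(voxOffset) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  data <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(data) != n) stop("truncated NIfTI data in ", path)
  list(data = array(data, dim = dims), pixdim = abs(pixdim))
}

#' Write a NIfTI-1 volume
#'
#' Minimal single-file NIfTI-1 writer; integer arrays are stored as int16,
#' doubles as float64.  Spacing goes to \code{pixdim} in mm.
#'
#' @param data 3D array.
#' @param path output path; \code{.gz} suffix enables gzip compression.
#' @param pixdim numeric length-3 voxel spacing in mm.
#' @return Invisibly, \code{path}.
#' @export
writeNifti <- function(data, path, pixdim = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3L, length(pixdim) == 3L, all(pixdim > 0))
  isInt <- is.integer(data) || all(data == round(data))
  datatype <- if (isInt) 4L else 64L
  bitpix <- if (isInt) 16L else 64L
  con <- .niftiConnection(path, "wb")
  on.exit(close(con))
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  w(348L, 4L)                                   # sizeof_hdr
  w(raw(36L), 1L)                               # unused through dim_info
  w(as.integer(c(3L, dim(data), 1L, 1L, 1L, 1L)), 2L)   # dim[8]
  w(raw(14L), 1L)                               # intent_p*, intent_code
  w(as.integer(datatype), 2L)                   # datatype
  w(as.integer(bitpix), 2L)                     # bitpix
  w(0L, 2L)                                     # slice_start
  writeBin(as.numeric(c(1, pixdim, 0, 0, 0, 0)), con, size = 4L,
           endian = "little")                   # pixdim[8]
  writeBin(352, con, size = 4L, endian = "little")      # vox_offset
  writeBin(c(0, 0), con, size = 4L, endian = "little")  # scl_slope/inter
  w(0L, 2L)                                     # slice_end
  writeBin(as.raw(0L), con)                     # slice_code
  writeBin(as.raw(2L), con)                     # xyzt_units = mm
  writeBin(rep(0, 4), con, size = 4L, endian = "little") # cal_max..toffset
  w(raw(8L), 1L)                                # glmax/glmin
  desc <- charToRaw("rvatlas label volume")
  w(c(desc, raw(80L - length(desc))), 1L)       # descrip
  w(raw(24L), 1L)                               # aux_file
  w(c(0L, 0L), 2L)                              # qform_code, sform_code
  writeBin(rep(0, 18), con, size = 4L, endian = "little") # quatern + srows
  w(raw(16L), 1L)                               # intent_name
  w(c(charToRaw("n+1"), as.raw(0L)), 1L)        # magic
  w(raw(4L), 1L)                                # extension flag
  if (isInt) {
    storage.mode(data) <- "integer"
    writeBin(as.vector(data), con, size = 2L, endian = "little")
  } else {
    writeBin(as.vector(as.numeric(data)), con, size = 8L, endian = "little")
  }
  invisible(path)
}
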