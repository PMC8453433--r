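#' Minimal NIfTI-1 input/output
#'
#' Single-file NIfTI-1 (`.nii`, `.nii.gz`) reading and writing for 3D
#' volumes, sufficient for the phantom/pipeline file interfaces of this
#' package. Supported on-disk datatypes: uint8 (2), int16 (4), int32 (8),
#' float32 (16), float64 (64). Data are written little-endian with
#' `vox_offset = 352` and no extensions; `scl_slope`/`scl_inter` are
#' honoured on read and written as 1/0.
#'
#' @param vol 3D numeric (or logical) array; a `pixdim` attribute (length-3
#'   numeric, mm) is used if `pixdim` is not given.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param pixdim voxel size in mm along the three axes.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns the
#'   array with attributes `pixdim` (mm) and `nifti_datatype`.
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' v <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
#' write_nifti(v, f, pixdim = c(1, 1, 3))
#' w <- read_nifti(f)
#' stopifnot(max(abs(v - w)) < 1e-6, all(attr(w, "pixdim") == c(1, 1, 3)))
#' @export
write_nifti <- function(vol, path, pixdim = attr(vol, "pixdim"),
                        datatype = "float32") {
  if (is.logical(vol)) {
    vol <- array(as.integer(vol), dim(vol))
    if (missing(datatype)) datatype <- "uint8"
  }
  if (length(dim(vol)) != 3L) stop("write_nifti: expected a 3D array")
  if (is.null(pixdim)) pixdim <- c(1, 1, 1)
  dt <- .nifti_dtypes[[datatype]]
  if (is.null(dt)) stop("write_nifti: unsupported datatype '", datatype, "'")

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wl <- function(x, size, what = "integer")
    writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
             con, size = size, endian = "little")

  wl(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type, db_name, extents, ...
  wl(c(3L, dim(vol), 1L, 1L, 1L, 1L), 2)        # dim[8]
  wl(c(0, 0, 0), 4, "double")                   # intent_p1..p3 (float32)
  wl(0L, 2)                                     # intent_code
  wl(dt$code, 2)                                # datatype
  wl(dt$bits, 2)                                # bitpix
  wl(0L, 2)                                     # slice_start
  wl(c(1, pixdim, 1, 1, 1, 1), 4, "double")     # pixdim[8]
  wl(352, 4, "double")                          # vox_offset
  wl(1, 4, "double")                            # scl_slope
  wl(0, 4, "double")                            # scl_inter
  wl(0L, 2); writeBin(raw(2), con)              # slice_end, slice_code, xyzt_units
  wl(c(0, 0, 0, 0), 4, "double")                # cal_max, cal_min, slice_duration, toffset
  wl(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(80 + 24), con)                   # descrip, aux_file
  wl(c(0L, 1L), 2)                              # qform_code, sform_code
  wl(rep(0, 6), 4, "double")                    # quatern b,c,d + offset x,y,z
  wl(c(pixdim[1], 0, 0, 0,  0, pixdim[2], 0, 0,  0, 0, pixdim[3], 0),
     4, "double")                               # srow_x/y/z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag

  x <- as.vector(vol)
  if (dt$what == "integer") {
    writeBin(as.integer(round(x)), con, size = dt$bytes, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = dt$bytes, endian = "little")
  }
  invisible(path)
}

.nifti_dtypes <- list(
  uint8   = list(code = 2L,  bits = 8L,  bytes = 1, what = "integer"),
  int16   = list(code = 4L,  bits = 16L, bytes = 2, what = "integer"),
  int32   = list(code = 8L,  bits = 32L, bytes = 4, what = "integer"),
  float32 = list(code = 16L, bits = 32L, bytes = 4, what = "double"),
  float64 = list(code = 64L, bits = 64L, bytes = 8, what = "double")
)

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  rl <- function(n, size, what = "integer", signed = TRUE)
    readBin(con, what, n = n, size = size, endian = "little", signed = signed)

  hdr_size <- rl(1, 4)
  if (!identical(hdr_size, 348L)) stop("read_nifti: not a NIfTI-1 file (or big-endian): ", path)
  invisible(readBin(con, "raw", 36))
  dims <- rl(8, 2)
  ndim <- dims[1]
  if (ndim < 3 || any(dims[5:8] > 1)) stop("read_nifti: only 3D volumes supported")
  shape <- dims[2:4]
  invisible(rl(3, 4, "double")); invisible(rl(1, 2))
  dtcode <- rl(1, 2)
  invisible(rl(2, 2))
  pixdim8 <- rl(8, 4, "double")
  vox_offset <- rl(1, 4, "double")
  scl_slope <- rl(1, 4, "double")
  scl_inter <- rl(1, 4, "double")
  # skip remainder of header up to vox_offset
  invisible(readBin(con, "raw", as.integer(vox_offset) - 120L))

  idx <- match(dtcode, vapply(.nifti_dtypes, function(d) d$code, integer(1)))
  if (is.na(idx)) stop("read_nifti: unsupported datatype code ", dtcode)
  dt <- .nifti_dtypes[[idx]]
  n <- prod(shape)
  x <- if (dt$what == "integer") {
    rl(n, dt$bytes, "integer", signed = dt$code != 2L)
  } else {
    rl(n, dt$bytes, "double")
  }
  if (length(x) != n) stop("read_nifti: truncated data in ", path)
  if (is.na(scl_slope) || scl_slope == 0) scl_slope <- 1
  if (is.na(scl_inter)) scl_inter <- 0
  if (scl_slope != 1 || scl_inter != 0) x <- x * scl_slope + scl_inter
  vol <- array(x, shape)
  attr(vol, "pixdim") <- pixdim8[2:4]
  attr(vol, "nifti_datatype") <- names(.nifti_dtypes)[idx]
  vol
}
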