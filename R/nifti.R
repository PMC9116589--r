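#' Minimal NIfTI-1 reader/writer
#'
#' Single-file NIfTI-1 (.nii, .nii.gz) support for the volume types this
#' pipeline exchanges: 3D/4D arrays of uint8, int16, int32, float32 or
#' float64, with the affine stored in the srow fields. This is deliberately
#' a minimal subset of the format (no extensions, no qform quaternions,
#' scl_slope/scl_inter honoured on read only).
#'
#' @param x numeric/integer array, 3 or 4 dimensions.
#' @param path output path; a ".gz" suffix triggers gzip compression.
#' @param affine 4x4 voxel-to-world matrix (row-major srow storage).
#' @param datatype one of "float32", "float64", "int16", "int32", "uint8".
#' @return `nii_write` returns `path` invisibly; `nii_read` returns a list
#'   with elements `data` (array), `affine` (4x4 matrix) and `datatype`.
#' @export
nii_write <- function(x, path, affine = diag(4),
                      datatype = c("float32", "int16", "uint8", "float64", "int32")) {
  datatype <- match.arg(datatype)
  stopifnot(is.array(x), length(dim(x)) %in% c(3L, 4L),
            is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  dt <- switch(datatype,
    uint8   = list(code = 2L,  bitpix = 8L,  size = 1L, what = "integer"),
    int16   = list(code = 4L,  bitpix = 16L, size = 2L, what = "integer"),
    int32   = list(code = 8L,  bitpix = 32L, size = 4L, what = "integer"),
    float32 = list(code = 16L, bitpix = 32L, size = 4L, what = "double"),
    float64 = list(code = 64L, bitpix = 64L, size = 8L, what = "double"))
  nd <- length(dim(x))
  dims <- rep(1L, 8L); dims[1L] <- nd; dims[seq_len(nd) + 1L] <- dim(x)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size = 4L) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)

  wi(348L)                       # sizeof_hdr
  wraw(36L)                      # data_type[10], db_name[18], extents, session_error, regular, dim_info
  wi(dims, 2L)                   # dim[8]
  wf(c(0, 0, 0))                 # intent_p1..p3
  wi(0L, 2L)                     # intent_code
  wi(dt$code, 2L); wi(dt$bitpix, 2L); wi(0L, 2L)   # datatype, bitpix, slice_start
  # pixdim[8]: qfac then voxel sizes from the affine column norms
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  wf(c(1, vox, rep(1, 4L)))
  wf(352)                        # vox_offset
  wf(c(1, 0))                    # scl_slope, scl_inter
  wi(0L, 2L); wraw(1L); wraw(1L) # slice_end, slice_code, xyzt_units
  wf(c(0, 0, 0))                 # cal_max, cal_min, slice_duration
  wf(0)                          # toffset
  wi(c(0L, 0L))                  # glmax, glmin
  wraw(80L + 24L)                # descrip, aux_file
  wi(c(0L, 2L), 2L)              # qform_code = 0, sform_code = 2 (aligned)
  wf(rep(0, 6))                  # quatern b,c,d + qoffset x,y,z
  wf(t(affine[1:3, ]))           # srow_x, srow_y, srow_z (row-major)
  wraw(16L)                      # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); wraw(1L)   # magic "n+1\0"
  wraw(4L)                       # pad to vox_offset 352

  if (dt$what == "integer") {
    writeBin(as.integer(x), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' @rdname nii_write
#' @export
nii_read <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri <- function(n, size = 4L, signed = TRUE)
    readBin(con, "integer", n = n, size = size, endian = "little", signed = signed)
  rf <- function(n, size = 4L)
    readBin(con, "double", n = n, size = size, endian = "little")

  hdr_size <- ri(1L)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file: ", path)
  invisible(readBin(con, "raw", 36L))
  dims <- ri(8L, 2L)
  rf(3L); ri(1L, 2L)
  datatype <- ri(1L, 2L); bitpix <- ri(1L, 2L); ri(1L, 2L)
  rf(8L)                         # pixdim
  vox_offset <- rf(1L)
  scl_slope <- rf(1L); scl_inter <- rf(1L)
  ri(1L, 2L); readBin(con, "raw", 2L)
  rf(4L); ri(2L)
  invisible(readBin(con, "raw", 104L))
  ri(2L, 2L); rf(6L)
  srow <- matrix(rf(12L), nrow = 3L, byrow = TRUE)
  invisible(readBin(con, "raw", 16L))
  magic <- rawToChar(readBin(con, "raw", 4L)[1:3])
  if (!identical(magic, "n+1")) stop("unsupported NIfTI magic: ", magic)
  invisible(readBin(con, "raw", as.integer(vox_offset) - 348L))

  nd <- dims[1L]; shape <- dims[seq_len(nd) + 1L]
  n <- prod(shape)
  dt_name <- switch(as.character(datatype),
    "2" = "uint8", "4" = "int16", "8" = "int32", "16" = "float32", "64" = "float64",
    stop("unsupported NIfTI datatype code: ", datatype))
  vals <- switch(dt_name,
    uint8   = ri(n, 1L, signed = FALSE),
    int16   = ri(n, 2L),
    int32   = ri(n, 4L),
    float32 = rf(n, 4L),
    float64 = rf(n, 8L))
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  affine <- rbind(srow, c(0, 0, 0, 1))
  list(data = array(vals, dim = shape), affine = affine, datatype = dt_name)
}
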