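# Minimal NIfTI-1 volume I/O (uncompressed .nii, single file).
#
# Scope: exactly what dense displacement-field volumes need — the 348-byte
# header, float32/float64 data, the sform affine, shapes X*Y*Z*3 or
# X*Y*Z*1*3.  Both endiannesses are read; files are written little-endian
# with datatype float64 so write/read round-trips are bit-exact.

NIFTI_DT_FLOAT32 <- 16L
NIFTI_DT_FLOAT64 <- 64L

read_nifti1 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    seek(con, 0)
    if (readBin(con, "integer", 1, size = 4, endian = endian) != 348L)
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  seek(con, 40)
  dim <- readBin(con, "integer", 8, size = 2, endian = endian)
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, size = 2, endian = endian)
  seek(con, 76)
  pixdim <- readBin(con, "double", 8, size = 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, size = 4, endian = endian)
  seek(con, 252)
  qform_code <- 0L  # quaternion form ignored; sform preferred
  sform_code <- readBin(con, "integer", 2, size = 2, endian = endian)[2]
  seek(con, 280)
  srow <- readBin(con, "double", 12, size = 4, endian = endian)
  seek(con, 344)
  magic <- readBin(con, "raw", 4)
  if (!identical(rawToChar(magic[1:3]), "n+1"))
    stop("unsupported NIfTI magic (only single-file n+1 supported): ", path)
  ndim <- dim[1]
  if (ndim < 1 || ndim > 7) stop("invalid NIfTI dim[0]: ", ndim)
  shape <- dim[2:(1 + ndim)]
  n <- prod(shape)
  size <- switch(as.character(datatype), "16" = 4L, "64" = 8L,
                 stop("unsupported NIfTI datatype ", datatype,
                      " (float32 and float64 only)"))
  seek(con, vox_offset)
  data <- readBin(con, "double", n, size = size, endian = endian)
  if (length(data) != n) stop("truncated NIfTI data in ", path)
  affine <- rbind(matrix(srow, 3, 4, byrow = TRUE), c(0, 0, 0, 1))
  if (sform_code == 0L) {
    affine <- diag(c(pixdim[2:4], 1))
  }
  list(data = array(data, dim = shape), affine = affine,
       pixdim = pixdim[2:(1 + min(ndim, 3))])
}

write_nifti1 <- function(data, affine, path) {
  stopifnot(is.array(data), all(is.finite(affine)), all(dim(affine) == c(4, 4)))
  shape <- dim(data)
  ndim <- length(shape)
  if (ndim > 7) stop("too many dimensions for NIfTI-1")
  dimv <- integer(8)
  dimv[1] <- ndim
  dimv[2:(1 + ndim)] <- shape
  dimv[dimv == 0L] <- 1L
  pixdim <- numeric(8)
  pixdim[2:4] <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4)                       # sizeof_hdr
  writeBin(raw(36), con)                              # data_type..dim_info
  writeBin(as.integer(dimv), con, size = 2)           # dim
  writeBin(numeric(3), con, size = 4)                 # intent_p1..p3
  writeBin(c(1007L, NIFTI_DT_FLOAT64, 64L, 0L), con, size = 2)  # intent(vector), datatype, bitpix, slice_start
  writeBin(pixdim, con, size = 4)                     # pixdim
  writeBin(352, con, size = 4)                        # vox_offset
  writeBin(c(1, 0), con, size = 4)                    # scl_slope, scl_inter
  writeBin(0L, con, size = 2)                         # slice_end
  writeBin(raw(2), con)                               # slice_code, xyzt_units
  writeBin(numeric(4), con, size = 4)                 # cal_max..toffset
  writeBin(c(0L, 0L), con, size = 4)                  # glmax, glmin
  writeBin(raw(104), con)                             # descrip, aux_file
  writeBin(c(0L, 1L), con, size = 2)                  # qform_code, sform_code
  writeBin(numeric(6), con, size = 4)                 # quaternion block
  writeBin(as.numeric(t(affine[1:3, ])), con, size = 4)  # srow_x/y/z
  writeBin(raw(16), con)                              # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)       # magic
  writeBin(raw(4), con)                               # extension flag
  writeBin(as.numeric(data), con, size = 8)
  invisible(path)
}
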