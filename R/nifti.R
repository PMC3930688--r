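# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# Little-endian and big-endian files are read; files are always written
# little-endian with vox_offset 352 and magic "n+1". Supported on-disk types:
# uint8 (2), int16 (4), int32 (8), float32 (16), float64 (64). scl_slope /
# scl_inter are applied on read and written as 1 / 0.

.nifti_types <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

.open_nii <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return list with `data` (numeric array, 3D or 4D), `pixdim` (voxel sizes
#'   in mm for the spatial axes) and `dim` (integer dimensions).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_nifti: no such file: %s", path))
  con <- .open_nii(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    if (sizeof_hdr == 1543569408L) endian <- "big"
    else stop(sprintf("read_nifti: %s is not a NIfTI-1 file", path))
  }
  invisible(readBin(con, "raw", 36L))               # header fields up to dim
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  invisible(readBin(con, "raw", 14L))               # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  invisible(readBin(con, "raw", 4L))                # bitpix, slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_slope <- readBin(con, "double", 1L, size = 4L, endian = endian)
  scl_inter <- readBin(con, "double", 1L, size = 4L, endian = endian)
  invisible(readBin(con, "raw", 224L))              # rest of header
  magic <- rawToChar(readBin(con, "raw", 4L)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("read_nifti: bad magic in %s", path))
  ndim <- dims[1]
  if (ndim < 3L || ndim > 4L)
    stop(sprintf("read_nifti: only 3D/4D images supported (got %dD)", ndim))
  shape <- dims[2:(1 + ndim)]
  ti <- match(datatype, .nifti_types$code)
  if (is.na(ti))
    stop(sprintf("read_nifti: unsupported datatype code %d", datatype))
  skip <- vox_offset - 348          # extension flag + any extensions
  if (skip > 0) invisible(readBin(con, "raw", as.integer(skip)))
  n <- prod(shape)
  vals <- readBin(con, .nifti_types$what[ti], n, size = .nifti_types$size[ti],
                  signed = .nifti_types$signed[ti], endian = endian)
  if (length(vals) != n)
    stop(sprintf("read_nifti: truncated data in %s", path))
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = shape),
       pixdim = pixdim[2:4],
       dim = as.integer(shape))
}

#' Write a NIfTI-1 volume
#'
#' @param data 3D or 4D numeric array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param pixdim spatial voxel sizes, mm (length 3).
#' @param datatype on-disk type: `"float64"` (default; lossless for R
#'   doubles), `"float32"`, `"int16"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = c(1, 1, 1),
                        datatype = c("float64", "float32", "int16", "uint8")) {
  datatype <- match.arg(datatype)
  if (!is.array(data) || !(length(dim(data)) %in% c(3L, 4L)))
    stop("write_nifti: data must be a 3D or 4D array")
  code <- switch(datatype, float64 = 64L, float32 = 16L, int16 = 4L,
                 uint8 = 2L)
  size <- switch(datatype, float64 = 8L, float32 = 4L, int16 = 2L, uint8 = 1L)
  what <- if (code %in% c(16L, 64L)) "double" else "integer"
  ndim <- length(dim(data))
  dims <- integer(8)
  dims[1] <- ndim
  dims[2:(1 + ndim)] <- dim(data)
  if (ndim == 3L) dims[5] <- 1L
  pd <- numeric(8)
  pd[1] <- 1
  pd[2:4] <- pixdim
  con <- .open_nii(path, "wb")
  on.exit(close(con))
  endian <- "little"
  writeBin(348L, con, size = 4L, endian = endian)
  writeBin(raw(36L), con)
  writeBin(as.integer(dims), con, size = 2L, endian = endian)
  writeBin(raw(14L), con)
  writeBin(code, con, size = 2L, endian = endian)
  writeBin(as.integer(size * 8L), con, size = 2L, endian = endian)  # bitpix
  writeBin(0L, con, size = 2L, endian = endian)                     # slice_start
  writeBin(pd, con, size = 4L, endian = endian)
  writeBin(352, con, size = 4L, endian = endian)                    # vox_offset
  writeBin(1, con, size = 4L, endian = endian)                      # scl_slope
  writeBin(0, con, size = 4L, endian = endian)                      # scl_inter
  writeBin(raw(224L), con)
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)
  writeBin(raw(4L), con)                                            # extension
  vals <- as.vector(data)
  if (what == "integer") vals <- as.integer(round(vals))
  writeBin(vals, con, size = size, endian = endian)
  invisible(path)
}
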