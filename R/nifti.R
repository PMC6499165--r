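# Minimal single-file NIfTI-1 codec (.nii, .nii.gz).
#
# Only what a structural head scan needs: the 348-byte header, the common
# scalar datatypes, voxel spacing from pixdim, and scl_slope/scl_inter
# rescaling.  Orientation matrices (qform/sform) are deliberately ignored:
# coordinates in this package live in scanner mm computed as
# 0-based voxel index * pixdim, with axis flips left to the caller.

NIFTI_DATATYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

#' Construct a head scan volume
#'
#' A `head_scan` couples a 3D grayscale array with its voxel spacing in mm.
#' Voxel `[i, j, k]` (1-based) sits at scanner position
#' `((i, j, k) - 1) * spacing` mm.
#'
#' @param data 3D numeric array of voxel intensities.
#' @param spacing numeric length-3, voxel edge lengths in mm.
#' @return An object of class `head_scan`.
#' @export
head_scan <- function(data, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L) stop_mm("value_error", "'data' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_mm("value_error", "'spacing' must be 3 positive voxel sizes in mm")
  }
  structure(list(data = data, spacing = spacing), class = "head_scan")
}

#' @export
print.head_scan <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<head_scan> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file `.nii` or `.nii.gz` structural scan. Only 3D scalar
#' volumes are supported; 4D files are reduced to their first volume.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [head_scan] with intensities rescaled by `scl_slope`/`scl_inter`
#'   when set.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_mm("io_error", sprintf("file not found: %s", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))

  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop_mm("io_error", "truncated NIfTI header")
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop_mm("io_error", "not a NIfTI-1 file (bad sizeof_hdr)")
  }
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dim_field  <- rd(40L, "integer", 8L, 2L)
  datatype   <- rd(70L, "integer", 1L, 2L)
  pixdim     <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope  <- rd(112L, "double", 1L, 4L)
  scl_inter  <- rd(116L, "double", 1L, 4L)
  magic      <- rawToChar(hdr_raw[345:348][hdr_raw[345:348] != as.raw(0)])
  if (!magic %in% c("n+1", "ni1")) stop_mm("io_error", "not a NIfTI-1 file (bad magic)")

  ndim <- dim_field[1]
  if (ndim < 3L) stop_mm("io_error", "NIfTI volume must be at least 3D")
  dims <- dim_field[2:4]
  spec <- NIFTI_DATATYPES[[as.character(datatype)]]
  if (is.null(spec)) stop_mm("io_error", sprintf("unsupported NIfTI datatype code %d", datatype))

  to_skip <- max(0, round(vox_offset) - 348L)
  if (to_skip > 0) readBin(con, "raw", n = to_skip)
  nvox <- prod(dims)
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < nvox) stop_mm("io_error", "truncated NIfTI data section")
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  spacing <- abs(pixdim[2:4])
  spacing[spacing == 0 | !is.finite(spacing)] <- 1
  head_scan(array(vals, dim = dims), spacing = spacing)
}

#' Write a NIfTI-1 volume
#'
#' Writes a [head_scan] as an uncompressed single-file `.nii` (float32).
#'
#' @param scan a [head_scan].
#' @param path output path ending in `.nii` (a `.nii.gz` path is honoured and
#'   gz-compressed).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(scan, path) {
  stopifnot(inherits(scan, "head_scan"))
  dims <- dim(scan$data)
  hdr <- raw(348L)
  put <- function(hdr, off, x, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0L, 348L, 4L)                             # sizeof_hdr
  hdr <- put(hdr, 40L, as.integer(c(3L, dims, 1L, 1L, 1L, 1L)), 2L)  # dim
  hdr <- put(hdr, 70L, 16L, 2L)                             # datatype float32
  hdr <- put(hdr, 72L, 32L, 2L)                             # bitpix
  hdr <- put(hdr, 76L, c(1, scan$spacing, 1, 1, 1, 1), 4L)  # pixdim
  hdr <- put(hdr, 108L, 352, 4L)                            # vox_offset
  hdr <- put(hdr, 112L, 1, 4L)                              # scl_slope
  hdr <- put(hdr, 116L, 0, 4L)                              # scl_inter
  magic <- c(charToRaw("n+1"), as.raw(0))
  hdr[345:348] <- magic

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)  # pad to vox_offset 352
  writeBin(as.numeric(scan$data), con, size = 4L, endian = "little")
  invisible(path)
}
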