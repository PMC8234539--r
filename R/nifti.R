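#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii`, `.nii.gz`). Only the
#' subset of the format the pipeline needs is supported: 3D volumes, scalar
#' datatypes (uint8, int16, int32, float32, float64), little- or big-endian,
#' with `pixdim` carrying the voxel spacing in mm. Written files use float32
#' (or uint8 for logical masks) at `vox_offset = 352`.
#'
#' No NIfTI package is assumed; the 348-byte header is read/written directly.
#'
#' @param file path ending in `.nii` or `.nii.gz`.
#' @return `read_nifti` returns a list with elements `data` (3D array) and
#'   `spacing` (numeric length-3, mm per axis).
#' @examples
#' f <- tempfile(fileext = ".nii.gz")
#' img <- array(rnorm(8 * 8 * 4), dim = c(8, 8, 4))
#' write_nifti(img, f, spacing = c(0.5, 0.5, 3))
#' rt <- read_nifti(f)
#' stopifnot(max(abs(rt$data - img)) < 1e-6, all(rt$spacing == c(0.5, 0.5, 3)))
#' @export
read_nifti <- function(file) {
  con <- if (grepl("\\.gz$", file)) gzfile(file, "rb") else file(file, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("not a NIfTI-1 file (truncated header): ", file)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", file)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic '", magic, "' in ", file)
  dim_field <- readBin(hdr_raw[41:56], "integer", n = 8, size = 2, endian = endian)
  ndim <- dim_field[1]
  if (ndim < 3L) stop("expected a 3D volume, got ", ndim, "D: ", file)
  shp <- dim_field[2:4]
  extra <- if (ndim > 3L) prod(pmax(dim_field[5:(ndim + 1)], 1L)) else 1L
  if (extra != 1L) stop("4D+ volumes are not supported: ", file)
  datatype <- readBin(hdr_raw[71:72], "integer", size = 2, endian = endian)
  pixdim <- readBin(hdr_raw[77:108], "double", n = 8, size = 4, endian = endian)
  vox_offset <- readBin(hdr_raw[109:112], "double", size = 4, endian = endian)
  scl_slope <- readBin(hdr_raw[113:116], "double", size = 4, endian = endian)
  scl_inter <- readBin(hdr_raw[117:120], "double", size = 4, endian = endian)
  n <- prod(shp)
  type <- switch(as.character(datatype),
    "2"  = list(what = "integer", size = 1, signed = FALSE),
    "4"  = list(what = "integer", size = 2, signed = TRUE),
    "8"  = list(what = "integer", size = 4, signed = TRUE),
    "16" = list(what = "double",  size = 4, signed = TRUE),
    "64" = list(what = "double",  size = 8, signed = TRUE),
    stop("unsupported NIfTI datatype code ", datatype, " in ", file)
  )
  skip <- max(0, round(vox_offset) - 348L)
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, type$what, n = n, size = type$size,
                  signed = type$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", file)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(as.double(vals), dim = shp),
       spacing = abs(pixdim[2:4]))
}

#' @rdname read_nifti
#' @param img 3D numeric or logical array.
#' @param spacing voxel spacing in mm per axis (length 3, positive).
#' @return `write_nifti` returns `file`, invisibly.
#' @export
write_nifti <- function(img, file, spacing = c(1, 1, 1)) {
  if (length(dim(img)) != 3L) stop("img must be a 3D array")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("spacing must be 3 positive numbers (mm)")
  }
  mask_like <- is.logical(img)
  datatype <- if (mask_like) 2L else 16L
  bitpix <- if (mask_like) 8L else 32L
  con <- if (grepl("\\.gz$", file)) gzfile(file, "wb") else file(file, "wb")
  on.exit(close(con))

  writeBin(348L, con, size = 4, endian = "little")          # sizeof_hdr
  writeBin(raw(35), con)                                    # data_type, db_name, extents...
  writeBin(as.raw(0L), con)                                 # dim_info
  writeBin(as.integer(c(3L, dim(img), 1L, 1L, 1L, 1L)), con, size = 2, endian = "little")
  writeBin(raw(14), con)                                    # intent_p1..p3, intent_code
  writeBin(datatype, con, size = 2, endian = "little")
  writeBin(bitpix, con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")            # slice_start
  writeBin(c(1, spacing, 0, 0, 0, 0), con, size = 4, endian = "little")  # pixdim
  writeBin(352, con, size = 4, endian = "little")           # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")       # scl_slope, scl_inter
  writeBin(raw(3), con)                                     # slice_end, slice_code
  writeBin(as.integer(2L), con, size = 1)                   # xyzt_units = mm
  writeBin(numeric(4), con, size = 4, endian = "little")    # cal_max, cal_min, slice_duration, toffset
  writeBin(c(0L, 0L), con, size = 4, endian = "little")     # glmax, glmin
  writeBin(raw(104), con)                                   # descrip + aux_file
  writeBin(c(0L, 0L), con, size = 2, endian = "little")     # qform_code, sform_code
  writeBin(numeric(18), con, size = 4, endian = "little")   # quatern/qoffset + srows
  writeBin(raw(16), con)                                    # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1), con)    # magic
  writeBin(raw(4), con)                                     # extension flag
  vals <- if (mask_like) as.integer(img) else as.double(img)
  if (mask_like) {
    writeBin(vals, con, size = 1)
  } else {
    writeBin(vals, con, size = 4, endian = "little")
  }
  invisible(file)
}
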