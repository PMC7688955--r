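#' NIfTI-1 input and output
#'
#' Minimal NIfTI-1 (.nii / .nii.gz) support covering the needs of this
#' package: single-file volumes, 3D or 4D payloads, little- or big-endian
#' headers, the common numeric datatypes, and `scl_slope`/`scl_inter`
#' rescaling. Spacing is taken from `pixdim` and the origin from the sform
#' row offsets (falling back to the quaternion offsets). No dependency on an
#' external imaging library is required, which keeps the package functional
#' in a fully offline environment.
#'
#' @name nifti_io
NULL

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`  = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`  = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16` = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64` = list(what = "double",  size = 8L, signed = TRUE)   # float64
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param component for a 4D file, the 1-based index of the 3D component to
#'   extract. Reading a 4D file without `component` is an error; use
#'   [read_volume_stack()] to read all components.
#' @return an [image_volume()].
#' @export
read_volume <- function(path, component = NULL) {
  vols <- read_volume_stack(path)
  if (length(vols) == 1L && is.null(component)) return(vols[[1L]])
  if (is.null(component))
    stop("file '", path, "' is 4D; supply 'component' or use read_volume_stack()")
  if (component < 1L || component > length(vols))
    stop("component ", component, " out of range 1..", length(vols))
  vols[[component]]
}

#' Read all 3D components of a NIfTI-1 file
#'
#' Multi-b-value diffusion acquisitions and dynamic contrast-enhanced series
#' are stored as 4D NIfTI; this returns them as a list of grid-compatible
#' [image_volume()] objects (a 3D file yields a length-1 list). The b-value
#' list or dynamic frame timing is configuration, not header, information.
#'
#' @inheritParams read_volume
#' @return list of `image_volume`.
#' @export
read_volume_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con), add = TRUE)
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L) stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported: ", path)

  rd_i16 <- function(off, n) readBin(raw_hdr[(off + 1L):(off + 2L * n)],
                                     "integer", n = n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(raw_hdr[(off + 1L):(off + 4L * n)],
                                     "double", n = n, size = 4L, endian = endian)
  dims <- rd_i16(40L, 8L)
  ndim <- dims[1L]
  if (!ndim %in% c(3L, 4L))
    stop("only 3D/4D NIfTI volumes are supported (got ", ndim, "D): ", path)
  shape <- dims[2:4]
  n4 <- if (ndim == 4L) max(1L, dims[5L]) else 1L
  datatype <- rd_i16(70L, 1L)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype, ": ", path)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  sform_code <- rd_i16(254L, 1L)
  qoffset <- rd_f32(268L, 3L)
  srow <- matrix(rd_f32(280L, 12L), nrow = 3L, byrow = TRUE)

  spacing <- abs(pixdim[2:4])
  origin <- if (sform_code > 0L) srow[, 4L] else qoffset
  nvox <- prod(shape) * n4
  skip <- round(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop("truncated NIfTI payload: ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  lapply(seq_len(n4), function(j) {
    block <- vals[((j - 1L) * prod(shape) + 1L):(j * prod(shape))]
    image_volume(array(block, shape), spacing = spacing, origin = origin)
  })
}

#' Write a volume (or stack of volumes) as NIfTI-1
#'
#' @param vol an [image_volume()], or a list of grid-compatible volumes
#'   (written as a 4D file).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param dtype on-disk storage: `"float64"` (lossless for doubles) or
#'   `"float32"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, dtype = c("float64", "float32")) {
  dtype <- match.arg(dtype)
  if (is_image_volume(vol)) vol <- list(vol)
  stopifnot(length(vol) >= 1L, all(vapply(vol, is_image_volume, logical(1))))
  if (length(vol) > 1L)
    for (j in 2:length(vol))
      if (!grid_compatible(vol[[1L]], vol[[j]]))
        stop("all components of a 4D write must be grid-compatible")
  parent <- dirname(path)
  if (!dir.exists(parent)) stop("parent directory does not exist: ", parent)
  if (dir.exists(path)) stop("path is a directory: ", path)

  shape <- dim(vol[[1L]]$values)
  n4 <- length(vol)
  spacing <- vol[[1L]]$spacing
  origin <- vol[[1L]]$origin
  code <- if (dtype == "float64") 64L else 16L
  bitpix <- if (dtype == "float64") 64L else 32L

  con <- nifti_connection(path, "wb")
  on.exit(close(con), add = TRUE)
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                                  # sizeof_hdr
  w_raw(36L)                                   # data_type..dim_info
  ndim <- if (n4 > 1L) 4L else 3L
  w_i16(c(ndim, shape, n4, 1L, 1L, 1L))        # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)                 # intent_p*, intent_code
  w_i16(code); w_i16(bitpix); w_i16(0L)        # datatype, bitpix, slice_start
  w_f32(c(1, spacing, 1, 0, 0, 0))             # pixdim[8]
  w_f32(352)                                   # vox_offset
  w_f32(1); w_f32(0)                           # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                         # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                         # cal_max..toffset
  w_i32(c(0L, 0L))                             # glmax, glmin
  w_raw(104L)                                  # descrip, aux_file
  w_i16(0L); w_i16(1L)                         # qform_code = 0, sform_code = 1
  w_f32(c(0, 0, 0)); w_f32(origin)             # quaterns, qoffsets
  w_f32(c(spacing[1], 0, 0, origin[1]))        # srow_x
  w_f32(c(0, spacing[2], 0, origin[2]))        # srow_y
  w_f32(c(0, 0, spacing[3], origin[3]))        # srow_z
  w_raw(16L)                                   # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  w_raw(4L)                                    # extension flag
  for (v in vol)
    writeBin(as.double(v$values), con, size = if (dtype == "float64") 8L else 4L,
             endian = "little")
  invisible(path)
}
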