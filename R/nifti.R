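# Minimal NIfTI-1 support. No R NIfTI package is available in the target
# environment, so the single-file (.nii / .nii.gz) format is handled here
# directly: 348-byte header, optional 4-byte extender, raster data in
# x-fastest order. Both endiannesses are read; files are written
# little-endian. Supported on-disk datatypes: uint8, int8, int16, uint16,
# int32, float32, float64, with scl_slope/scl_inter applied on read.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "double",  size = 4L, signed = TRUE),
  `64`  = list(what = "double",  size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE))

read_nifti_header <- function(con) {
  raw348 <- readBin(con, "raw", 348L)
  if (length(raw348) < 348L) stop("unreadable file: truncated NIfTI header")
  rd <- function(off, what, n, size, endian) {
    readBin(raw348[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rd(0L, "integer", 1L, 4L, endian) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 1L, 4L, endian) != 348L)
      stop("unreadable file: not a NIfTI-1 header (sizeof_hdr != 348)")
  }
  magic <- rawToChar(raw348[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unreadable file: bad NIfTI magic string")
  list(
    dim = rd(40L, "integer", 8L, 2L, endian),
    datatype = rd(70L, "integer", 1L, 2L, endian),
    bitpix = rd(72L, "integer", 1L, 2L, endian),
    pixdim = rd(76L, "double", 8L, 4L, endian),
    vox_offset = rd(108L, "double", 1L, 4L, endian),
    scl_slope = rd(112L, "double", 1L, 4L, endian),
    scl_inter = rd(116L, "double", 1L, 4L, endian),
    magic = magic, endian = endian, raw = raw348)
}

read_nifti_array <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- read_nifti_header(con)
  nd <- hdr$dim[1L]
  if (nd < 1L || nd > 7L) stop("unreadable file: bad dim[0]")
  dims <- hdr$dim[2L:(1L + nd)]
  dt <- NIFTI_DT[[as.character(hdr$datatype)]]
  if (is.null(dt)) stop(sprintf("unsupported NIfTI datatype %d", hdr$datatype))
  skip <- round(hdr$vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(dims)
  x <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
               endian = hdr$endian)
  if (length(x) < n) stop("unreadable file: truncated NIfTI data")
  x <- as.double(x)
  sl <- hdr$scl_slope; ic <- hdr$scl_inter
  if (is.finite(sl) && sl != 0 && !(sl == 1 && ic == 0)) x <- x * sl + ic
  list(data = array(x, dim = dims), header = hdr)
}

#' Read a 4D NIfTI image as a voxels-by-time matrix
#'
#' Loads a 4D NIfTI-1 volume (`.nii` or `.nii.gz`), optionally restricted to
#' a 3D brain mask (nonzero voxels are in-mask), and flattens it to an
#' I x T matrix in x-fastest voxel order. The volume geometry and raw header
#' are retained so that derived maps (A/D/S variance images) can be written
#' back in the input grid.
#'
#' @param path 4D NIfTI file.
#' @param mask_path optional 3D NIfTI mask matching the first three
#'   dimensions of `path`.
#' @return object of class `dse_raw`: list with `values` (I_raw x T matrix),
#'   `geometry` (list: `dim3`, `pixdim`, `mask_idx` — linear voxel indices
#'   into the 3D grid — and the raw input `header` for round-trip writing),
#'   and `T`.
#' @export
read_nifti_4d <- function(path, mask_path = NULL) {
  img <- read_nifti_array(path)
  nd <- length(dim(img$data))
  if (nd != 4L) stop(sprintf("not a 4D image: %s has %d dimension(s)", path, nd))
  d <- dim(img$data)
  mask_idx <- seq_len(prod(d[1:3]))
  if (!is.null(mask_path)) {
    msk <- read_nifti_array(mask_path)
    if (length(dim(msk$data)) != 3L ||
        !all(dim(msk$data) == d[1:3]))
      stop(sprintf("dimension mismatch: mask %s does not match image grid %s",
                   paste(dim(msk$data), collapse = "x"),
                   paste(d[1:3], collapse = "x")))
    mask_idx <- which(as.vector(msk$data) != 0)
    if (!length(mask_idx)) stop("empty mask: no nonzero mask voxels")
  }
  mat <- matrix(img$data, nrow = prod(d[1:3]), ncol = d[4L])[mask_idx, ,
                                                             drop = FALSE]
  structure(list(
    values = mat,
    geometry = list(dim3 = d[1:3], pixdim = img$header$pixdim,
                    mask_idx = mask_idx, header = img$header$raw),
    T = d[4L]
  ), class = "dse_raw")
}

# Compose a fresh little-endian NIfTI-1 header for the given dims (float64).
make_nifti_header <- function(dims, pixdim = NULL) {
  nd <- length(dims)
  dimfield <- integer(8L); dimfield[1L] <- nd
  dimfield[2L:(1L + nd)] <- as.integer(dims)
  dimfield[dimfield == 0L] <- 1L
  pd <- numeric(8L); pd[2L:8L] <- 1
  if (!is.null(pixdim)) pd[seq_along(pixdim)] <- pixdim
  con <- rawConnection(raw(0L), "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wr <- function(n) writeBin(raw(n), con)
  wi(348L, 4L)                      # sizeof_hdr
  wr(34L)                           # data_type, db_name, extents, session_error
  writeBin(charToRaw("r"), con)     # regular
  wr(1L)                            # dim_info
  wi(dimfield, 2L)                  # dim[8]
  wf(c(0, 0, 0))                    # intent_p1..p3
  wi(0L, 2L)                        # intent_code
  wi(64L, 2L)                       # datatype: float64
  wi(64L, 2L)                       # bitpix
  wi(0L, 2L)                        # slice_start
  wf(pd)                            # pixdim[8]
  wf(352)                           # vox_offset
  wf(1); wf(0)                      # scl_slope, scl_inter
  wi(0L, 2L); wr(1L)                # slice_end, slice_code
  writeBin(as.raw(10L), con)        # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4L)                 # glmax, glmin
  wr(80L + 24L)                     # descrip, aux_file
  wi(c(0L, 1L), 2L)                 # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))          # quatern b,c,d, qoffset x,y,z
  wf(c(pd[2L], 0, 0, 0))            # srow_x
  wf(c(0, pd[3L], 0, 0))            # srow_y
  wf(c(0, 0, pd[4L], 0))            # srow_z
  wr(16L)                           # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  rawConnectionValue(con)
}

# Patch an existing raw header to new dims / float64 storage.
patch_nifti_header <- function(raw348, dims) {
  nd <- length(dims)
  dimfield <- integer(8L); dimfield[1L] <- nd
  dimfield[2L:(1L + nd)] <- as.integer(dims)
  dimfield[dimfield == 0L] <- 1L
  put <- function(h, off, bytes) { h[(off + 1L):(off + length(bytes))] <- bytes; h }
  le <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                   endian = "little")
  lef <- function(x) writeBin(as.double(x), raw(), size = 4L, endian = "little")
  h <- raw348
  h <- put(h, 40L, le(dimfield, 2L))
  h <- put(h, 70L, le(64L, 2L))
  h <- put(h, 72L, le(64L, 2L))
  h <- put(h, 108L, lef(352))
  h <- put(h, 112L, lef(1)); h <- put(h, 116L, lef(0))
  h <- put(h, 344L, c(charToRaw("n+1"), as.raw(0L)))
  h
}

#' Write an array as a NIfTI-1 file
#'
#' Writes a 3D or 4D numeric array as a single-file little-endian NIfTI-1
#' volume with float64 storage (lossless for doubles). When a `geometry`
#' from [read_nifti_4d()] is supplied, its header is reused (patched for the
#' new dimensions) so outputs live in the input grid; note header reuse
#' assumes a little-endian source file.
#'
#' @param x numeric array (3D or 4D), or a numeric vector together with
#'   `geometry` (it is then scattered into the 3D grid at
#'   `geometry$mask_idx`, zero elsewhere).
#' @param path output file name (`.nii`; a `.gz` suffix gzip-compresses).
#' @param geometry optional geometry list from [read_nifti_4d()].
#' @param pixdim optional voxel dimensions (length 8 NIfTI pixdim, or the
#'   leading entries thereof) when writing without a geometry.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, geometry = NULL, pixdim = NULL) {
  if (!is.null(geometry) && is.null(dim(x))) {
    vol <- numeric(prod(geometry$dim3))
    vol[geometry$mask_idx] <- x
    x <- array(vol, dim = geometry$dim3)
  }
  if (is.null(dim(x))) stop("x must be an array, or a vector with a geometry")
  dims <- dim(x)
  hdr <- if (!is.null(geometry) && !is.null(geometry$header)) {
    patch_nifti_header(geometry$header, dims)
  } else {
    make_nifti_header(dims, pixdim %||% (if (!is.null(geometry)) geometry$pixdim))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)  # extender
  writeBin(as.double(as.vector(x)), con, size = 8L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
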