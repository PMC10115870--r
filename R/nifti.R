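#' Minimal NIfTI-1 volume IO
#'
#' Self-contained NIfTI-1 (.nii / .nii.gz) reading and writing for 3D scalar
#' volumes. Geometry is taken from the sform when `sform_code > 0`, else from
#' the qform quaternion, else from `pixdim` alone. Supported on read:
#' uint8, int16, int32, float32, float64, with `scl_slope`/`scl_inter`
#' applied; both byte orders. Written files are float64, sform-coded, one
#' 3D frame.
#'
#' @name nifti_io
NULL

NIFTI_HDR_SIZE <- 348L

#' Read a NIfTI-1 volume
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a `vol_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")  # transparently handles uncompressed files too
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", NIFTI_HDR_SIZE)
  if (length(raw_hdr) < NIFTI_HDR_SIZE)
    stop("malformed NIfTI file (truncated header): ", path, call. = FALSE)

  endian <- "little"
  sizeof_hdr <- readBin(raw_hdr[1:4], "integer", 1, 4, endian = endian)
  if (sizeof_hdr != NIFTI_HDR_SIZE) {
    endian <- "big"
    sizeof_hdr <- readBin(raw_hdr[1:4], "integer", 1, 4, endian = endian)
    if (sizeof_hdr != NIFTI_HDR_SIZE)
      stop("malformed NIfTI file (field sizeof_hdr != 348): ", path,
           call. = FALSE)
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("malformed NIfTI file (field magic is not 'n+1'/'ni1'): ", path,
         call. = FALSE)

  i16 <- function(at, n = 1) readBin(raw_hdr[at + seq_len(2 * n)], "integer",
                                     n, 2, endian = endian)
  f32 <- function(at, n = 1) readBin(raw_hdr[at + seq_len(4 * n)], "double",
                                     n, 4, endian = endian)
  dim_ <- i16(40, 8)
  ndim <- dim_[1]
  if (ndim < 3L) stop("malformed NIfTI file (field dim[0] < 3): ", path,
                      call. = FALSE)
  extent <- dim_[2:(1 + ndim)]
  if (ndim > 3L && prod(extent[-(1:3)]) != 1L)
    stop("only 3D NIfTI volumes are supported: ", path, call. = FALSE)
  shape <- extent[1:3]
  datatype <- i16(70)
  pixdim <- f32(76, 8)
  vox_offset <- f32(108)
  scl_slope <- f32(112); scl_inter <- f32(116)
  qform_code <- i16(252); sform_code <- i16(254)

  affine <- if (sform_code > 0L) {
    rbind(f32(280, 4), f32(296, 4), f32(312, 4), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    quatern_affine(b = f32(256), c = f32(260), d = f32(264),
                   offset = c(f32(268), f32(272), f32(276)),
                   pixdim = pixdim[2:4], qfac = ifelse(pixdim[1] < 0, -1, 1))
  } else {
    a <- diag(4); diag(a)[1:3] <- abs(pixdim[2:4]); a
  }

  spec <- nifti_datatype(datatype, path)
  skip <- as.integer(round(vox_offset)) - NIFTI_HDR_SIZE
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, spec$what, n, spec$size, signed = spec$signed,
                  endian = endian)
  if (length(vals) < n)
    stop("malformed NIfTI file (truncated data): ", path, call. = FALSE)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  new_volume(new_grid(shape, affine), vals)
}

nifti_datatype <- function(code, path) {
  switch(as.character(code),
    "2"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "integer", size = 2L, signed = TRUE),
    "8"  = list(what = "integer", size = 4L, signed = TRUE),
    "16" = list(what = "double",  size = 4L, signed = TRUE),
    "64" = list(what = "double",  size = 8L, signed = TRUE),
    stop("unsupported NIfTI datatype code ", code, " in ", path,
         call. = FALSE))
}

quatern_affine <- function(b, c, d, offset, pixdim, qfac) {
  a2 <- 1 - b^2 - c^2 - d^2
  a <- sqrt(max(a2, 0))
  R <- rbind(
    c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),     2 * (b * d + a * c)),
    c(2 * (b * c + a * d),   a^2 + c^2 - b^2 - d^2,   2 * (c * d - a * b)),
    c(2 * (b * d - a * c),   2 * (c * d + a * b),     a^2 + d^2 - b^2 - c^2))
  R <- R %*% diag(c(abs(pixdim[1:2]), abs(pixdim[3]) * qfac))
  rbind(cbind(R, offset), c(0, 0, 0, 1))
}

#' Write a volume as NIfTI-1
#' @param vol a `vol_volume`.
#' @param path destination `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "vol_volume"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  e <- "little"
  hdr <- raw(NIFTI_HDR_SIZE)
  put <- function(hdr, at, bytes) { hdr[at + seq_along(bytes)] <- bytes; hdr }
  w_i32 <- function(x) writeBin(as.integer(x), raw(), 4L, endian = e)
  w_i16 <- function(x) writeBin(as.integer(x), raw(), 2L, endian = e)
  w_f32 <- function(x) writeBin(as.numeric(x), raw(), 4L, endian = e)

  sh <- vol$grid$shape
  aff <- vol$grid$affine
  hdr <- put(hdr, 0L,   w_i32(NIFTI_HDR_SIZE))
  hdr <- put(hdr, 40L,  w_i16(c(3L, sh, 1L, 1L, 1L, 1L)))
  hdr <- put(hdr, 70L,  w_i16(64L))                       # datatype float64
  hdr <- put(hdr, 72L,  w_i16(64L))                       # bitpix
  hdr <- put(hdr, 76L,  w_f32(c(1, vol$grid$voxel_size_mm, 0, 0, 0, 0)))
  hdr <- put(hdr, 108L, w_f32(352))                       # vox_offset
  hdr <- put(hdr, 112L, w_f32(c(1, 0)))                   # scl_slope/inter
  hdr <- put(hdr, 123L, as.raw(10L))                      # xyzt_units: mm
  hdr <- put(hdr, 252L, w_i16(c(0L, 2L)))                 # qform 0, sform 2
  hdr <- put(hdr, 280L, w_f32(aff[1, ]))
  hdr <- put(hdr, 296L, w_f32(aff[2, ]))
  hdr <- put(hdr, 312L, w_f32(aff[3, ]))
  hdr <- put(hdr, 344L, c(charToRaw("n+1"), as.raw(0L)))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                                  # extension flag
  writeBin(as.numeric(vol$values), con, 8L, endian = e)
  invisible(path)
}
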