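# Minimal NIfTI-1 input/output.
#
# Only what the pipeline needs: single-file .nii / .nii.gz, 3-D (or 4-D with
# a trailing vector dimension for displacement fields), the common scalar
# datatypes, scl_slope/scl_inter scaling, and the sform/qform affine. Written
# from the NIfTI-1 header layout; no external imaging package is required.

NIFTI_DT <- list(
  uint8  = list(code = 2L,   bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16  = list(code = 4L,   bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32  = list(code = 8L,   bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE),
  uint16 = list(code = 512L, bitpix = 16L, what = "integer", size = 2L, signed = FALSE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

# Build the qform rotation from the quaternion fields (method 2 of the
# NIfTI-1 reference).
qform_affine <- function(b, c, d, qoffset, pixdim, qfac) {
  a2 <- 1 - b * b - c * c - d * d
  a <- if (a2 < 0) 0 else sqrt(a2)
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c + a * d), 2 * (b * d - a * c),
    2 * (b * c - a * d), a * a + c * c - b * b - d * d, 2 * (c * d + a * b),
    2 * (b * d + a * c), 2 * (c * d - a * b), a * a + d * d - c * c - b * b
  ), nrow = 3)
  if (qfac == 0) qfac <- 1
  R <- R %*% diag(c(pixdim[1], pixdim[2], qfac * pixdim[3]))
  aff <- diag(4)
  aff[1:3, 1:3] <- R
  aff[1:3, 4] <- qoffset
  aff
}

#' Read a NIfTI-1 volume
#'
#' Reads `.nii` or `.nii.gz`. 3-D images come back as an [mri_volume]; a 4-D
#' image with a small 4th dimension (such as a displacement field) comes back
#' as a list of `mri_volume`s, one per 4th-dimension component.
#'
#' @param path file path.
#' @return an `mri_volume`, or a list of them for 4-D input.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("read_nifti: no such file: ", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("read_nifti: truncated header in ", path)
  endian <- .Platform$endian
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- if (endian == "little") "big" else "little"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stop("read_nifti: not a NIfTI-1 file: ", path)
  }
  rd <- function(off, what, n, size, signed = TRUE) {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("read_nifti: bad magic in ", path)
  dims <- rd(40, "integer", 8, 2)
  datatype <- rd(70, "integer", 1, 2)
  pixdim <- rd(76, "double", 8, 4)
  vox_offset <- rd(108, "double", 1, 4)
  scl_slope <- rd(112, "double", 1, 4)
  scl_inter <- rd(116, "double", 1, 4)
  qform_code <- rd(252, "integer", 1, 2)
  sform_code <- rd(254, "integer", 1, 2)
  quat <- rd(256, "double", 6, 4)
  srow <- matrix(rd(280, "double", 12, 4), nrow = 3, byrow = TRUE)

  nd <- dims[1]
  if (nd < 3 || nd > 4) stop("read_nifti: only 3-D/4-D images supported")
  shape <- dims[2:(1 + nd)]
  dt <- Filter(function(d) d$code == datatype, NIFTI_DT)
  if (!length(dt)) stop("read_nifti: unsupported datatype code ", datatype)
  dt <- dt[[1]]

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("read_nifti: truncated data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter

  affine <- if (sform_code > 0) {
    rbind(cbind(srow[, 1:3], srow[, 4]), c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    qform_affine(quat[1], quat[2], quat[3], quat[4:6], pixdim[2:4], pixdim[1])
  } else {
    a <- diag(c(abs(pixdim[2:4]), 1)); a
  }
  if (nd == 3) {
    mri_volume(array(vals, dim = shape), affine = affine)
  } else {
    lapply(seq_len(shape[4]), function(t) {
      block <- vals[((t - 1) * prod(shape[1:3]) + 1):(t * prod(shape[1:3]))]
      mri_volume(array(block, dim = shape[1:3]), affine = affine)
    })
  }
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file `.nii` (or `.nii.gz` when the path ends in `.gz`)
#' with the volume's affine stored in the sform. `NA` voxels are written as
#' NaN for float datatypes and 0 for integer datatypes.
#'
#' @param vol an [mri_volume], or a list of same-geometry `mri_volume`s
#'   (written as a 4-D image, e.g. a displacement field).
#' @param path output path.
#' @param datatype one of `"float32"` (default), `"float64"`, `"uint8"`,
#'   `"int16"`, `"int32"`, `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = "float32") {
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("write_nifti: unsupported datatype ", datatype)
  vols <- if (inherits(vol, "mri_volume")) list(vol) else vol
  stopifnot(length(vols) >= 1, inherits(vols[[1]], "mri_volume"))
  affine <- vols[[1]]$affine
  dm <- dim(vols[[1]]$data)
  nd <- if (length(vols) > 1) 4L else 3L
  dims <- c(nd, dm, if (nd == 4L) length(vols) else 1L, 1L, 1L, 1L)[1:8]
  dims <- c(dims, rep(1L, 8 - length(dims)))
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))

  hdr <- raw(348)
  put <- function(off, vals, what, size) {
    b <- writeBin(if (what == "integer") as.integer(vals) else as.double(vals),
                  raw(), size = size, endian = .Platform$endian)
    hdr[(off + 1):(off + length(b))] <<- b
  }
  put(0, 348L, "integer", 4)                       # sizeof_hdr
  hdr[39 + 1] <- as.raw(0)                          # dim_info
  put(40, dims, "integer", 2)                       # dim
  put(70, dt$code, "integer", 2)                    # datatype
  put(72, dt$bitpix, "integer", 2)                  # bitpix
  put(76, c(1, spacing, rep(1, 4)), "double", 4)    # pixdim (qfac = 1)
  put(108, 352, "double", 4)                        # vox_offset
  put(112, 1, "double", 4)                          # scl_slope
  put(116, 0, "double", 4)                          # scl_inter
  put(123, 10L, "integer", 1)                       # xyzt_units: mm | sec
  put(252, 0L, "integer", 2)                        # qform_code
  put(254, 1L, "integer", 2)                        # sform_code = scanner
  put(280, t(affine[1:3, , drop = FALSE]), "double", 4)  # srow_x/y/z
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))    # magic

  con <- nifti_open(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(hdr, con)
  writeBin(raw(4), con)                             # extension flag
  for (v in vols) {
    vals <- as.vector(v$data)
    if (dt$what == "integer") {
      vals[!is.finite(vals)] <- 0
      writeBin(as.integer(round(vals)), con, size = dt$size,
               endian = .Platform$endian)
    } else {
      vals[is.na(vals)] <- NaN
      writeBin(as.double(vals), con, size = dt$size,
               endian = .Platform$endian)
    }
  }
  invisible(path)
}
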