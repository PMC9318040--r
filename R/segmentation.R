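#' @title Liver masks
#'
#' @description
#' Clinical-grade liver segmentation is delegated to externally supplied
#' masks (the original system used an unpublished learned segmenter). The
#' built-in [segment_phantom()] is a classical intensity-based segmenter
#' adequate for the package's digital phantoms only, and is documented as
#' such. Masks are used as given: whether major vessels or lesions were
#' excluded upstream is the mask producer's responsibility.
#' @name segmentation
NULL

#' Load a liver mask
#'
#' Reads a binary or label image, selects a label if requested, binarizes,
#' and aligns it to an expected grid by nearest-neighbour resampling.
#'
#' @param path NIfTI file, or an `mri_volume` already in memory.
#' @param expected_geometry target grid (`mri_volume` or `vol_geometry`);
#'   `NULL` keeps the native grid.
#' @param label_id when given, the mask is `voxels == label_id`; otherwise
#'   any value > 0.5 is foreground.
#' @return a binary `mri_volume`.
#' @export
load_mask <- function(path, expected_geometry = NULL, label_id = NULL) {
  vol <- if (inherits(path, "mri_volume")) path else read_nifti(path)
  d <- vol$data
  d[is.na(d)] <- 0
  bin <- if (is.null(label_id)) d > 0.5 else abs(d - label_id) < 0.5
  m <- mri_volume(array(as.double(bin), dim = dim(d)), affine = vol$affine)
  if (!is.null(expected_geometry) && !same_geometry(m, expected_geometry)) {
    n_before <- sum(m$data)
    m <- resample_to(m, expected_geometry, "nearest")
    m$data[is.na(m$data)] <- 0
    if (n_before > 0) {
      frac_kept <- sum(m$data) * voxel_volume_mm3(m) /
        (n_before * voxel_volume_mm3(vol))
      if (frac_kept < 0.95)
        warning(sprintf("load_mask: >5%% of the mask falls outside the target field of view (kept %.1f%%)",
                        100 * frac_kept))
    }
  }
  if (sum(m$data) == 0) stop("load_mask: mask is empty")
  m
}

#' Phantom-only intensity segmentation
#'
#' Otsu threshold, largest 6-connected component, morphological closing and
#' hole filling. Intended for the package's synthetic phantoms, where liver
#' and background are bimodal by construction; it is NOT a clinical liver
#' segmenter.
#'
#' @param image `mri_volume` with bright liver on darker background (e.g. a
#'   hepatobiliary-phase image or an inverted post-contrast T1 map).
#' @param closing_iter closing radius in voxels (6-connectivity iterations).
#' @return a binary `mri_volume`.
#' @export
segment_phantom <- function(image, closing_iter = 1L) {
  d <- image$data
  d[is.na(d)] <- min(d, na.rm = TRUE)
  thr <- otsu_threshold(d)
  fg <- d > thr
  if (!any(fg)) stop("segment_phantom: no foreground above the Otsu threshold")
  fg <- largest_component(fg)
  fg <- binary_close(fg, closing_iter)
  fg <- fill_holes(fg)
  mri_volume(array(as.double(fg), dim = dim(fg)), affine = image$affine)
}

#' Mask volume in millilitres
#'
#' Voxel count times voxel volume; the `livervolume` input to the
#' patient-specific factor.
#'
#' @param mask binary `mri_volume`.
#' @return volume in mL.
#' @export
mask_volume_ml <- function(mask) {
  n <- sum(mask$data > 0.5, na.rm = TRUE)
  n * voxel_volume_mm3(mask) / 1000
}

# Dice overlap of two binary volumes on one grid (used by phantom QA tests).
dice_coefficient <- function(a, b) {
  x <- a$data > 0.5 & !is.na(a$data)
  y <- b$data > 0.5 & !is.na(b$data)
  2 * sum(x & y) / (sum(x) + sum(y))
}
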