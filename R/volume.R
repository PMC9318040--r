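#' @title Volumetric image container
#'
#' @description
#' `mri_volume` is the package's in-memory representation of a 3-D scalar
#' image: a numeric array plus an affine mapping voxel indices to world
#' (scanner) coordinates in millimetres. All quantitative maps (T1, B1,
#' reduction-rate), masks and proton-density images are `mri_volume`s; maps
#' carry voxel validity as `NA` entries, which every downstream operation
#' treats as "excluded from analysis".
#'
#' The voxel-index convention is 0-based: voxel `(0,0,0)` maps to the world
#' point `affine %*% c(0,0,0,1)`. R arrays are 1-based, so element
#' `data[i,j,k]` corresponds to voxel `(i-1, j-1, k-1)`.
#'
#' @param data numeric 3-D array; `NA` marks invalid/excluded voxels.
#' @param spacing per-axis voxel spacing in mm (length 3, all > 0).
#' @param origin world coordinate (mm) of voxel (0,0,0).
#' @param affine optional 4x4 voxel-to-world matrix; overrides
#'   `spacing`/`origin` when given.
#' @return an object of class `mri_volume`.
#' @export
mri_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("mri_volume: `data` must be a 3-D array")
  if (is.null(affine)) {
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("mri_volume: spacings must be three finite positive numbers")
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine[1:3, 1:3])) < 1e-12)
      stop("mri_volume: affine must be an invertible 4x4 matrix")
  }
  structure(list(data = data, affine = affine), class = "mri_volume")
}

#' @export
print.mri_volume <- function(x, ...) {
  d <- dim(x$data)
  sp <- vol_spacing(x)
  cat(sprintf("<mri_volume %dx%dx%d, spacing %.2fx%.2fx%.2f mm, %d/%d valid>\n",
              d[1], d[2], d[3], sp[1], sp[2], sp[3],
              sum(!is.na(x$data)), length(x$data)))
  invisible(x)
}

#' Per-axis voxel spacing (mm) of a volume or geometry
#' @param vol an `mri_volume` or `vol_geometry`.
#' @return numeric length-3 vector of spacings.
#' @export
vol_spacing <- function(vol) {
  a <- vol$affine[1:3, 1:3]
  sqrt(colSums(a^2))
}

#' Voxel volume in cubic millimetres
#' @param vol an `mri_volume` or `vol_geometry`.
#' @export
voxel_volume_mm3 <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' Grid geometry without pixel data
#'
#' A lightweight description of a sampling grid (dimensions + affine), used
#' as a resampling target.
#'
#' @inheritParams mri_volume
#' @param dim integer voxel counts per axis.
#' @return an object of class `vol_geometry`.
#' @export
vol_geometry <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         affine = NULL) {
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  }
  structure(list(dim = as.integer(dim), affine = as.matrix(affine)),
            class = "vol_geometry")
}

#' Extract the grid geometry of a volume
#' @param vol an `mri_volume`.
#' @export
geometry_of <- function(vol) {
  if (inherits(vol, "vol_geometry")) return(vol)
  vol_geometry(dim(vol$data), affine = vol$affine)
}

geom_dim <- function(g) if (inherits(g, "vol_geometry")) g$dim else dim(g$data)

#' Test whether two volumes/geometries share a grid
#' @param a,b `mri_volume` or `vol_geometry` objects.
#' @param tol tolerance on affine entries (mm).
#' @export
same_geometry <- function(a, b, tol = 1e-4) {
  all(geom_dim(a) == geom_dim(b)) &&
    max(abs(a$affine - b$affine)) <= tol
}

is_axis_aligned <- function(aff) {
  all(aff[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] == 0)
}

# voxel (0-based, possibly fractional) -> world mm. idx: n x 3 matrix.
voxel_to_world <- function(vol, idx) {
  aff <- vol$affine
  if (is_axis_aligned(aff)) {
    d <- diag(aff[1:3, 1:3])
    return(cbind(idx[, 1] * d[1] + aff[1, 4],
                 idx[, 2] * d[2] + aff[2, 4],
                 idx[, 3] * d[3] + aff[3, 4]))
  }
  idx <- rbind(t(idx), 1)
  t(aff %*% idx)[, 1:3, drop = FALSE]
}

# world mm -> voxel (0-based fractional). pts: n x 3 matrix.
world_to_voxel <- function(vol, pts) {
  aff <- vol$affine
  if (is_axis_aligned(aff)) {
    d <- diag(aff[1:3, 1:3])
    return(cbind((pts[, 1] - aff[1, 4]) / d[1],
                 (pts[, 2] - aff[2, 4]) / d[2],
                 (pts[, 3] - aff[3, 4]) / d[3]))
  }
  inv <- solve(aff)
  pts <- rbind(t(pts), 1)
  t(inv %*% pts)[, 1:3, drop = FALSE]
}

# Matrix (n x 3) of 0-based voxel coordinates for every voxel of a grid,
# in R array order (first index fastest).
grid_voxel_coords <- function(dm) {
  cbind(
    rep.int(seq_len(dm[1]) - 1L, dm[2] * dm[3]),
    rep.int(rep(seq_len(dm[2]) - 1L, each = dm[1]), dm[3]),
    rep(seq_len(dm[3]) - 1L, each = dm[1] * dm[2])
  )
}

# Trilinear interpolation of a 3-D array at fractional 0-based voxel
# coordinates (n x 3). Values outside the array, or touching an NA corner,
# come back NA. Vectorized over points.
interp_trilinear <- function(arr, vox) {
  dm <- dim(arr)
  eps <- 1e-6
  x <- vox[, 1]; y <- vox[, 2]; z <- vox[, 3]
  out <- rep(NA_real_, length(x))
  inside <- x >= -eps & x <= dm[1] - 1 + eps & y >= -eps & y <= dm[2] - 1 + eps &
    z >= -eps & z <= dm[3] - 1 + eps & is.finite(x) & is.finite(y) & is.finite(z)
  if (!any(inside)) return(out)
  x <- pmin(pmax(x[inside], 0), dm[1] - 1)
  y <- pmin(pmax(y[inside], 0), dm[2] - 1)
  z <- pmin(pmax(z[inside], 0), dm[3] - 1)
  x0 <- pmin(floor(x), dm[1] - 2); x0[dm[1] == 1] <- 0
  y0 <- pmin(floor(y), dm[2] - 2); y0[dm[2] == 1] <- 0
  z0 <- pmin(floor(z), dm[3] - 2); z0[dm[3] == 1] <- 0
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  sx <- if (dm[1] > 1) 1L else 0L
  sy <- if (dm[2] > 1) 1L else 0L
  sz <- if (dm[3] > 1) 1L else 0L
  # linear index of corner (x0, y0, z0), 1-based
  base <- 1 + x0 + dm[1] * (y0 + dm[2] * z0)
  off <- function(dx, dy, dz) arr[base + dx * sx + dm[1] * (dy * sy + dm[2] * (dz * sz))]
  v <- off(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    off(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    off(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    off(1, 1, 0) * fx * fy * (1 - fz) +
    off(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    off(1, 0, 1) * fx * (1 - fy) * fz +
    off(0, 1, 1) * (1 - fx) * fy * fz +
    off(1, 1, 1) * fx * fy * fz
  out[inside] <- v
  out
}

# Nearest-neighbour interpolation at fractional 0-based voxel coordinates.
interp_nearest <- function(arr, vox) {
  dm <- dim(arr)
  eps <- 1e-6
  i <- round(vox[, 1]); j <- round(vox[, 2]); k <- round(vox[, 3])
  out <- rep(NA_real_, nrow(vox))
  inside <- i >= -eps & i <= dm[1] - 1 + eps & j >= -eps & j <= dm[2] - 1 + eps &
    k >= -eps & k <= dm[3] - 1 + eps & is.finite(i) & is.finite(j) & is.finite(k)
  i <- pmin(pmax(i[inside], 0), dm[1] - 1)
  j <- pmin(pmax(j[inside], 0), dm[2] - 1)
  k <- pmin(pmax(k[inside], 0), dm[3] - 1)
  out[inside] <- arr[1 + i + dm[1] * (j + dm[2] * k)]
  out
}

#' Sample a volume at world coordinates
#'
#' @param vol an `mri_volume`.
#' @param points_mm n x 3 matrix of world coordinates.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return numeric vector of sampled values; `NA` outside the field of view.
#' @export
sample_world <- function(vol, points_mm, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  vox <- world_to_voxel(vol, points_mm)
  if (interpolation == "linear") interp_trilinear(vol$data, vox)
  else interp_nearest(vol$data, vox)
}

#' Resample a volume onto a target grid
#'
#' Values are interpolated at the world position of each target voxel.
#' Linear interpolation propagates invalidity: any target voxel whose
#' interpolation stencil touches an invalid (`NA`) source voxel is invalid.
#' Voxels outside the source field of view are invalid.
#'
#' @param map an `mri_volume`.
#' @param target an `mri_volume` or `vol_geometry` defining the output grid.
#' @param interpolation `"linear"` (default for continuous maps) or
#'   `"nearest"` (masks, labels).
#' @return an `mri_volume` on the target grid.
#' @export
resample_to <- function(map, target, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  g <- geometry_of(target)
  if (same_geometry(map, g)) {
    return(mri_volume(map$data, affine = map$affine))
  }
  dm <- geom_dim(g)
  vox_t <- grid_voxel_coords(dm)
  pts <- voxel_to_world(list(affine = g$affine), vox_t)
  vals <- sample_world(map, pts, interpolation)
  mri_volume(array(vals, dim = dm), affine = g$affine)
}

# Bounding-box geometry: isotropic grid of `spacing_mm` covering the TRUE
# region of `mask` (an mri_volume with 0/1 data) plus `pad_mm` margin.
iso_grid_over_mask <- function(mask, spacing_mm, pad_mm = spacing_mm) {
  idx <- which(mask$data > 0.5 & !is.na(mask$data))
  if (!length(idx)) stop("iso_grid_over_mask: empty mask")
  dm <- dim(mask$data)
  coord <- arrayInd(idx, dm) - 1L
  corners <- voxel_to_world(mask, rbind(apply(coord, 2, min), apply(coord, 2, max)))
  lo <- pmin(corners[1, ], corners[2, ]) - pad_mm
  hi <- pmax(corners[1, ], corners[2, ]) + pad_mm
  n <- pmax(1L, as.integer(ceiling((hi - lo) / spacing_mm)) + 1L)
  vol_geometry(n, spacing = rep(spacing_mm, 3), origin = lo)
}
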