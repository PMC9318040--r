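#' @title Variable-flip-angle T1 mapping
#'
#' @description
#' T1 relaxometry from spoiled-gradient-echo (SPGR) magnitude images at two
#' or more flip angles. The SPGR steady-state signal is
#' \deqn{S(\alpha) = M_0 \sin\alpha \frac{1 - E_1}{1 - E_1 \cos\alpha},
#'       \quad E_1 = e^{-TR/T1}.}
#' Writing \eqn{y = S/\sin\alpha} and \eqn{x = S/\tan\alpha} turns this into
#' a straight line \eqn{y = E_1 x + M_0 (1 - E_1)}: the classic linearized
#' DESPOT1 estimator. The slope gives \eqn{T1 = -TR / \ln(E_1)} and the
#' intercept the proton density. B1 transmit inhomogeneity is corrected by
#' scaling the nominal angles voxel-wise with a supplied relative-B1 map;
#' estimating B1 itself is out of scope.
#' @name t1map
NULL

T1_VALID_RANGE_MS <- c(1, 5000)

#' Bundle a multi-flip-angle SPGR series
#'
#' @param volumes list of `mri_volume`s (magnitude images), one per angle,
#'   all on one grid.
#' @param flip_angles_deg nominal flip angles (degrees), same length.
#' @param tr_ms repetition time (ms), > 0.
#' @return an object of class `vfa_series`.
#' @export
vfa_series <- function(volumes, flip_angles_deg, tr_ms) {
  if (length(volumes) != length(flip_angles_deg))
    stop("vfa_series: one volume per flip angle required")
  if (length(unique(flip_angles_deg)) < 2)
    stop("vfa_series: at least 2 distinct flip angles required")
  if (!is.finite(tr_ms) || tr_ms <= 0)
    stop("vfa_series: tr_ms must be positive")
  g <- geometry_of(volumes[[1]])
  for (v in volumes[-1])
    if (!same_geometry(v, g))
      stop("vfa_series: all volumes must share one geometry")
  structure(list(volumes = volumes, flip_angles_deg = flip_angles_deg,
                 tr_ms = tr_ms),
            class = "vfa_series")
}

#' Fit a T1 map from a variable-flip-angle series
#'
#' Voxel-wise linearized DESPOT1 regression of `S/sin(a)` on `S/tan(a)`
#' across the angles (least squares when more than two angles are given).
#' Voxels whose slope falls outside (0, 1), whose fitted T1 leaves the
#' physically plausible window of 1-5000 ms, or whose signal is entirely
#' zero are flagged invalid (`NA`) rather than silently clipped.
#'
#' @param series a [vfa_series()].
#' @param b1 optional relative-B1 map (`mri_volume`, values near 1): the
#'   effective angle at a voxel is `b1 * nominal angle`. Resampled onto the
#'   series grid automatically; must overlap it.
#' @return list with `t1`: T1 map (`mri_volume`, ms, `NA` where invalid),
#'   `m0`: proton-density map, `n_invalid`: invalid-voxel count.
#' @export
fit_t1_vfa <- function(series, b1 = NULL) {
  stopifnot(inherits(series, "vfa_series"))
  g <- geometry_of(series$volumes[[1]])
  dmv <- geom_dim(g)
  nvox <- prod(dmv)
  na <- length(series$flip_angles_deg)
  ang <- series$flip_angles_deg * pi / 180

  b1v <- NULL
  if (!is.null(b1)) {
    if (!same_geometry(b1, g)) b1 <- resample_to(b1, g, "linear")
    b1v <- as.vector(b1$data)
    if (all(is.na(b1v)))
      stop("fit_t1_vfa: B1 map does not overlap the series field of view")
    if (any(b1v <= 0 | b1v > 2, na.rm = TRUE))
      stop("fit_t1_vfa: relative B1 values must lie in (0, 2]")
  }

  # running sums for the per-voxel regression of y on x
  sx <- sy <- sxx <- sxy <- numeric(nvox)
  smax <- numeric(nvox)
  for (k in seq_len(na)) {
    S <- as.vector(series$volumes[[k]]$data)
    a_eff <- if (is.null(b1v)) rep(ang[k], nvox) else ang[k] * b1v
    x <- S / tan(a_eff)
    y <- S / sin(a_eff)
    sx <- sx + x; sy <- sy + y
    sxx <- sxx + x * x; sxy <- sxy + x * y
    smax <- pmax(smax, abs(S))
  }
  denom <- na * sxx - sx * sx
  slope <- (na * sxy - sx * sy) / denom
  intercept <- (sy - slope * sx) / na

  t1 <- -series$tr_ms / log(slope)
  m0 <- intercept / (1 - slope)
  bad <- !is.finite(slope) | slope <= 0 | slope >= 1 | smax == 0 |
    !is.finite(t1) | t1 < T1_VALID_RANGE_MS[1] | t1 > T1_VALID_RANGE_MS[2]
  t1[bad] <- NA_real_
  m0[bad] <- NA_real_
  list(
    t1 = mri_volume(array(t1, dim = dmv), affine = g$affine),
    m0 = mri_volume(array(m0, dim = dmv), affine = g$affine),
    n_invalid = sum(bad)
  )
}

#' SPGR steady-state signal
#'
#' The forward model used both by the phantom simulator and in tests.
#'
#' @param t1_ms T1 (ms); may be a vector/array.
#' @param m0 equilibrium magnetization (a.u.).
#' @param alpha_deg flip angle (degrees), scalar.
#' @param tr_ms repetition time (ms).
#' @param b1 relative flip-angle scale (default 1).
#' @return signal magnitude(s).
#' @export
spgr_signal <- function(t1_ms, m0, alpha_deg, tr_ms, b1 = 1) {
  a <- alpha_deg * pi / 180 * b1
  e1 <- exp(-tr_ms / t1_ms)
  m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
}
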