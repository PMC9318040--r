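#' @title Digital liver phantom
#'
#' @description
#' Generates synthetic patients and paired pre/post-contrast liver T1
#' volumes so the whole scoring pipeline is testable without clinical data.
#' The stated world of the generator: anthropometrics around the reference
#' cohort (height 1.70 +/- 0.08 m, weight 83 +/- 16 kg, liver volume
#' 1513 +/- 415 mL), MELD labs drawn log-normally and rejection-sampled into
#' the requested severity band (normal MELD <= 10, impaired 11-18, severe
#' > 18), and group-calibrated fractional contrast uptake decreasing with
#' severity (means 0.54 / 0.43 / 0.31).
#'
#' The uptake model defines the post-contrast map as
#' `T1_post = T1_pre * (1 - uptake)` composed with a smooth random
#' deformation, which makes the voxel reduction rate equal `100 * uptake`
#' exactly — an analytic ground truth for every downstream stage.
#' @name phantom
NULL

# Group calibration: fractional-uptake mean/sd per MELD severity group,
# chosen so the whole-liver percent reduction rate reproduces the reference
# per-group summaries (54 +/- 10, 43 +/- 12, 31 +/- 14 %).
PHANTOM_UPTAKE_CALIBRATION <- list(
  normal   = c(mean = 0.54, sd = 0.10),
  impaired = c(mean = 0.43, sd = 0.12),
  severe   = c(mean = 0.31, sd = 0.14)
)

# Liver-volume sampling centres (mL) with a disease-severity shift; the
# weighted mean over a 132/59/4 cohort stays close to 1513 mL.
PHANTOM_VOLUME_CENTRES <- c(normal = 1540, impaired = 1460, severe = 1250)

# Log-normal lab centres per group feeding the MELD rejection sampler.
PHANTOM_LAB_PARAMS <- list(
  normal   = list(bili = c(log(0.7), 0.35), inr = c(log(1.05), 0.06),
                  creat = c(log(0.9), 0.20)),
  impaired = list(bili = c(log(2.0), 0.45), inr = c(log(1.35), 0.12),
                  creat = c(log(1.2), 0.30)),
  severe   = list(bili = c(log(5.0), 0.35), inr = c(log(1.9), 0.12),
                  creat = c(log(2.2), 0.25))
)

#' Phantom specification
#'
#' Defaults describe a coarse abdominal field of view that comfortably holds
#' an average liver: 64 x 64 x 48 voxels at 4 mm. Native liver T1 of 800 ms
#' and a 1200 ms background give the bimodal contrast the phantom segmenter
#' relies on.
#'
#' @param grid_shape voxel counts per axis.
#' @param voxel_spacing_mm per-axis spacing (mm), all > 0.
#' @param field_strength_T 1.5 or 3.0 (metadata only; no per-field model).
#' @param t1_liver_baseline_ms mean native liver T1 (ms).
#' @param t1_background_ms surrounding-tissue T1 (ms).
#' @param uptake_mean mean fractional contrast uptake, in [0, 1).
#' @param uptake_sd spatial standard deviation of the regional-uptake field.
#' @param uptake_texture_scale_mm correlation length (FWHM, mm) of the
#'   regional-function texture.
#' @param deformation_amplitude_mm maximum inter-phase displacement of the
#'   smooth random (breathing-like) deformation component (mm).
#' @param bulk_shift_mm length-3 inter-phase bulk translation (mm),
#'   emulating patient repositioning between the native and hepatobiliary
#'   acquisitions; recovered by the rigid registration stage.
#' @param noise_sd image-noise standard deviation relative to the median
#'   synthesized signal magnitude (i.e. 1/SNR).
#' @param blur_vox partial-volume band limit: Gaussian sigma (voxels)
#'   applied to the pre-contrast map before the post map is composed.
#' @param seed integer RNG seed; identical spec + seed reproduce outputs
#'   bit-identically.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 48),
                         voxel_spacing_mm = c(4, 4, 4),
                         field_strength_T = 3.0,
                         t1_liver_baseline_ms = 800,
                         t1_background_ms = 1200,
                         uptake_mean = 0.5,
                         uptake_sd = 0.08,
                         uptake_texture_scale_mm = 30,
                         deformation_amplitude_mm = 5,
                         bulk_shift_mm = c(0, 0, 0),
                         noise_sd = 0.02,
                         blur_vox = 1.0,
                         seed = 1L) {
  if (any(voxel_spacing_mm <= 0)) stop("phantom_spec: spacings must be > 0")
  if (uptake_mean < 0 || uptake_mean >= 1)
    stop("phantom_spec: uptake_mean must lie in [0, 1)")
  if (noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
  if (!field_strength_T %in% c(1.5, 3.0))
    stop("phantom_spec: field strength must be 1.5 or 3.0 T")
  structure(list(
    grid_shape = as.integer(grid_shape),
    voxel_spacing_mm = voxel_spacing_mm,
    field_strength_T = field_strength_T,
    t1_liver_baseline_ms = t1_liver_baseline_ms,
    t1_background_ms = t1_background_ms,
    uptake_mean = uptake_mean,
    uptake_sd = uptake_sd,
    uptake_texture_scale_mm = uptake_texture_scale_mm,
    deformation_amplitude_mm = deformation_amplitude_mm,
    bulk_shift_mm = rep(bulk_shift_mm, length.out = 3),
    noise_sd = noise_sd,
    blur_vox = blur_vox,
    seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Sample a synthetic patient record
#'
#' Labs are rejection-sampled (bounded at 1000 attempts) until the computed
#' MELD score falls in the requested severity band, so the record's group
#' membership is guaranteed by construction.
#'
#' @param meld_group_target `"normal"`, `"impaired"` or `"severe"`.
#' @param seed integer RNG seed.
#' @param id patient identifier string.
#' @return one-row `data.frame` with demographics, labs, dialysis flag,
#'   liver volume (mL) and the group-calibrated target uptake fraction.
#' @export
make_patient <- function(meld_group_target = c("normal", "impaired", "severe"),
                         seed = 1L, id = NULL) {
  grp <- match.arg(meld_group_target)
  rng <- local_rng(seed)
  sex <- if (stats::runif(1) < 0.79) "M" else "F"
  age <- clamp(round(stats::rnorm(1, 62, 11)), 20, 90)
  height <- clamp(stats::rnorm(1, 1.70, 0.08), 1.45, 2.00)
  weight <- clamp(stats::rnorm(1, 83, 16), 45, 140)
  lp <- PHANTOM_LAB_PARAMS[[grp]]
  band <- switch(grp, normal = c(6, 10), impaired = c(11, 18), severe = c(19, 40))
  ok <- FALSE
  for (i in seq_len(1000)) {
    bili <- stats::rlnorm(1, lp$bili[1], lp$bili[2])
    inr <- stats::rlnorm(1, lp$inr[1], lp$inr[2])
    creat <- stats::rlnorm(1, lp$creat[1], lp$creat[2])
    dialysis <- grp == "severe" && stats::runif(1) < 0.05
    m <- meld(bili, inr, creat, dialysis)
    if (m >= band[1] && m <= band[2]) { ok <- TRUE; break }
  }
  if (!ok)
    stop("make_patient: could not realize a MELD score in the '", grp,
         "' band after 1000 attempts")
  vol <- clamp(stats::rnorm(1, PHANTOM_VOLUME_CENTRES[[grp]], 400), 700, 2800)
  cal <- PHANTOM_UPTAKE_CALIBRATION[[grp]]
  uptake <- clamp(stats::rnorm(1, cal["mean"], cal["sd"]), 0.02, 0.93)
  data.frame(
    id = if (is.null(id)) sprintf("P%s_%04d", toupper(substr(grp, 1, 1)), seed) else id,
    sex = sex, age_years = age,
    height_m = height, weight_kg = weight,
    bilirubin_mg_dl = bili, inr = inr, creatinine_mg_dl = creat,
    dialysis = dialysis,
    liver_volume_ml = vol,
    meld = m, meld_group = grp,
    target_uptake = unname(uptake),
    stringsAsFactors = FALSE
  )
}

# Implicit ellipsoid-union liver at a global scale `s` (mm); returns the
# logical mask on the grid. Two overlapping ellipsoids give a crude
# two-lobed liver shape.
liver_shape_mask <- function(coords_mm, centre_mm, s) {
  axes1 <- c(1.00, 0.80, 0.55) * s
  axes2 <- c(0.55, 0.50, 0.45) * s
  c2 <- centre_mm + c(0.62, 0.30, 0.10) * s
  q1 <- ((coords_mm[, 1] - centre_mm[1]) / axes1[1])^2 +
    ((coords_mm[, 2] - centre_mm[2]) / axes1[2])^2 +
    ((coords_mm[, 3] - centre_mm[3]) / axes1[3])^2
  q2 <- ((coords_mm[, 1] - c2[1]) / axes2[1])^2 +
    ((coords_mm[, 2] - c2[2]) / axes2[2])^2 +
    ((coords_mm[, 3] - c2[3]) / axes2[3])^2
  q1 <= 1 | q2 <= 1
}

# Zero-mean, unit-variance smooth random field on the grid.
smooth_noise_field <- function(dm, spacing, scale_mm) {
  sigma_vox <- (scale_mm / 2.355) / spacing   # FWHM -> sigma
  f <- gaussian_smooth3(array(stats::rnorm(prod(dm)), dim = dm), sigma_vox)
  (f - mean(f)) / stats::sd(f)
}

# Smooth random displacement field with max magnitude = amplitude_mm.
# Each component is a Gaussian-correlated random field whose correlation
# length is kept at >= 6x the amplitude, which bounds the field's Lipschitz
# constant well below 1 so the map x -> x + d(x) stays invertible (and the
# fixed-point inversion used during phantom generation converges).
random_deformation <- function(dm, affine, amplitude_mm, scale_mm = 60,
                               spacing = NULL) {
  if (is.null(spacing)) spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (amplitude_mm <= 0) {
    z <- array(0, dim = dm)
    return(deformation_field(z, z, z, affine))
  }
  scale_mm <- max(scale_mm, 6 * amplitude_mm)
  comp <- lapply(1:3, function(i) smooth_noise_field(dm, spacing, scale_mm))
  mag <- sqrt(comp[[1]]^2 + comp[[2]]^2 + comp[[3]]^2)
  sc <- amplitude_mm / max(mag)
  deformation_field(comp[[1]] * sc, comp[[2]] * sc, comp[[3]] * sc, affine)
}

#' Generate ground truth for one phantom patient
#'
#' Builds the liver mask (ellipsoid-union shape binary-searched to the
#' patient's liver volume within 0.5%), the spatially correlated fractional
#' uptake field (mean `uptake_mean`, clipped to [0, 0.95]), the noiseless
#' pre-contrast T1 map (liver baseline with 3% smooth texture, uniform
#' background, plus a small bright spleen-like distractor), the
#' post-contrast map `T1_pre * (1 - uptake)` rendered in the deformed
#' post-phase geometry, and the deformation mapping post-grid points to
#' pre-grid points.
#'
#' @param spec a [phantom_spec()].
#' @param patient one-row record from [make_patient()]; its `target_uptake`
#'   (when present) overrides `spec$uptake_mean`.
#' @return list of class `phantom_truth` with `t1_pre`, `t1_post`,
#'   `uptake`, `deformation`, `mask`, `hbp` (hepatobiliary-phase-like
#'   weighted image), `m0`, `patient`, `spec`.
#' @export
make_ground_truth <- function(spec, patient) {
  stopifnot(inherits(spec, "phantom_spec"))
  rng <- local_rng(spec$seed)
  dm <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  affine <- diag(c(sp, 1))
  affine[1:3, 4] <- -(dm - 1) * sp / 2   # grid centred on the world origin

  uptake_mean <- spec$uptake_mean
  if (!is.null(patient$target_uptake) && !is.na(patient$target_uptake))
    uptake_mean <- patient$target_uptake

  geom <- list(affine = affine)
  coords <- voxel_to_world(geom, grid_voxel_coords(dm))
  centre <- c(0, 0, 0)
  target_ml <- patient$liver_volume_ml
  vox_ml <- prod(sp) / 1000

  # binary search the global shape scale to hit the requested volume;
  # the union shape holds roughly 2.0 * s^3 mm^3, giving a tight bracket
  s_est <- (target_ml * 1000 / 2.0)^(1 / 3)
  lo <- 0.75 * s_est; hi <- min(1.3 * s_est, min(dm * sp) * 0.75)
  vol_at <- function(s) sum(liver_shape_mask(coords, centre, s)) * vox_ml
  if (vol_at(hi) < target_ml)
    stop("make_ground_truth: requested liver volume does not fit the grid")
  if (vol_at(lo) > target_ml) lo <- 10
  for (i in 1:22) {
    mid <- (lo + hi) / 2
    if (vol_at(mid) < target_ml) lo <- mid else hi <- mid
  }
  s <- hi
  mask_l <- array(liver_shape_mask(coords, centre, s), dim = dm)
  got_ml <- sum(mask_l) * vox_ml
  if (abs(got_ml - target_ml) / target_ml > 0.02)
    stop(sprintf("make_ground_truth: realizable volume %.0f mL misses target %.0f mL by > 2%%",
                 got_ml, target_ml))
  border <- mask_l
  border[2:(dm[1] - 1), 2:(dm[2] - 1), 2:(dm[3] - 1)] <- FALSE
  if (any(border))
    stop("make_ground_truth: liver touches the grid border; enlarge the grid")

  # spleen-like bright distractor: small sphere tucked beside the liver
  spleen_c <- centre + c(-0.95, -0.75, 0) * s
  spleen_r <- 0.22 * s
  dist2 <- (coords[, 1] - spleen_c[1])^2 + (coords[, 2] - spleen_c[2])^2 +
    (coords[, 3] - spleen_c[3])^2
  spleen <- array(dist2 <= spleen_r^2, dim = dm) & !mask_l

  # vessel-like structures: ~5% of the liver carries blood-pool signal and
  # takes up no hepatocyte contrast, so it stays visible in BOTH phases —
  # the contrast-stable anatomy that makes deformable registration
  # well-posed. Soft (ramped) weights emulate partial-volume edges.
  vfield <- smooth_noise_field(dm, sp, spec$uptake_texture_scale_mm / 2)
  q <- stats::quantile(vfield[mask_l], c(0.94, 0.985))
  w_vessel <- clamp((vfield - q[1]) / (q[2] - q[1]), 0, 1)
  w_vessel[!mask_l] <- 0

  # regional-uptake field: smooth, clipped to [0, 0.95], suppressed in
  # vessels, renormalized so the whole-mask mean equals uptake_mean
  u <- smooth_noise_field(dm, sp, spec$uptake_texture_scale_mm)
  u <- uptake_mean + spec$uptake_sd * u
  u <- pmin(pmax(u, 0), 0.95)
  u <- u * (1 - w_vessel)
  u[!mask_l] <- 0
  if (uptake_mean > 0 && mean(u[mask_l]) > 0) {
    u <- pmin(u * (uptake_mean / mean(u[mask_l])), 0.95)
    # one more pass: clipping after rescale can leave a small deficit
    if (mean(u[mask_l]) > 0)
      u <- pmin(u * (uptake_mean / mean(u[mask_l])), 0.95)
  }

  # pre-contrast T1: textured liver over uniform background; vessels carry
  # long blood-pool T1. A mild blur (0.7 voxel) emulates the partial-volume
  # band limit of real acquisitions; it is applied BEFORE the post map is
  # composed, so T1_post = T1_pre * (1 - uptake) holds exactly voxel-wise.
  tex <- smooth_noise_field(dm, sp, spec$uptake_texture_scale_mm)
  t1_pre <- array(spec$t1_background_ms, dim = dm)
  t1_pre[mask_l] <- spec$t1_liver_baseline_ms * (1 + 0.03 * tex[mask_l])
  t1_pre <- t1_pre * (1 - w_vessel) +
    w_vessel * spec$t1_liver_baseline_ms * 1.8
  t1_pre[spleen] <- spec$t1_liver_baseline_ms * 0.55
  t1_pre <- gaussian_smooth3(t1_pre, spec$blur_vox)

  t1_clean_post <- t1_pre * (1 - u)

  # deformation d maps post-grid points to pre-grid points:
  # T1_post(y) = T1_clean_post(psi(y)) with psi(y) = y - d(psi(y)), so that
  # sampling T1_post at y + d(y) recovers T1_clean_post(y).
  def <- random_deformation(dm, affine, spec$deformation_amplitude_mm,
                            spacing = sp)
  bulk <- spec$bulk_shift_mm
  if (is.null(bulk)) bulk <- c(0, 0, 0)
  if (any(bulk != 0))
    def <- deformation_field(def$dx_vol$data + bulk[1],
                             def$dy_vol$data + bulk[2],
                             def$dz_vol$data + bulk[3], affine)
  if (spec$deformation_amplitude_mm > 0 || any(bulk != 0)) {
    psi <- coords
    for (it in 1:10) {
      dx <- cbind(sample_world(def$dx_vol, psi), sample_world(def$dy_vol, psi),
                  sample_world(def$dz_vol, psi))
      dx[is.na(dx)] <- 0
      psi <- coords - dx
    }
    vol_clean <- mri_volume(t1_clean_post, affine = affine)
    post_vals <- sample_world(vol_clean, psi)
    post_vals[is.na(post_vals)] <- spec$t1_background_ms
    t1_post <- array(post_vals, dim = dm)
  } else {
    t1_post <- t1_clean_post
  }

  m0 <- array(1000, dim = dm)
  hbp <- array(spgr_signal(t1_post, m0, 15, 5), dim = dm)

  structure(list(
    t1_pre = mri_volume(t1_pre, affine = affine),
    t1_post = mri_volume(t1_post, affine = affine),
    t1_post_clean = mri_volume(t1_clean_post, affine = affine),
    uptake = mri_volume(u, affine = affine),
    deformation = def,
    mask = mri_volume(array(as.double(mask_l), dim = dm), affine = affine),
    hbp = mri_volume(hbp, affine = affine),
    m0 = mri_volume(m0, affine = affine),
    patient = patient,
    spec = spec
  ), class = "phantom_truth")
}

#' Synthesize a variable-flip-angle SPGR series from a truth T1 map
#'
#' Evaluates the SPGR signal equation per voxel and angle, scales the
#' nominal angles by an optional relative-B1 map, and corrupts magnitudes
#' with Rician noise (Gaussian or none available for linear-regime tests).
#'
#' @param t1_truth T1 map (`mri_volume`, ms).
#' @param m0 proton-density map (`mri_volume` or scalar).
#' @param flip_angles_deg at least two distinct nominal angles (degrees).
#' @param tr_ms repetition time (ms).
#' @param b1 optional relative-B1 `mri_volume`.
#' @param noise_sd noise standard deviation relative to the median
#'   noiseless signal across the series (1/SNR).
#' @param seed integer RNG seed.
#' @param noise_model `"rician"` (magnitude MR data), `"gaussian"`, or
#'   `"none"`.
#' @return a [vfa_series()].
#' @export
synthesize_vfa <- function(t1_truth, m0 = 1000, flip_angles_deg = c(2, 15),
                           tr_ms = 5, b1 = NULL, noise_sd = 0, seed = 1L,
                           noise_model = c("rician", "gaussian", "none")) {
  noise_model <- match.arg(noise_model)
  if (length(unique(flip_angles_deg)) < 2)
    stop("synthesize_vfa: at least 2 distinct flip angles required")
  if (tr_ms <= 0) stop("synthesize_vfa: tr_ms must be positive")
  rng <- local_rng(seed)
  dm <- dim(t1_truth$data)
  m0a <- if (inherits(m0, "mri_volume")) m0$data else array(m0, dim = dm)
  b1a <- if (is.null(b1)) 1 else b1$data
  # noise scaled to the typical signal level so noise_sd = 1/SNR
  clean <- lapply(flip_angles_deg, function(a)
    spgr_signal(t1_truth$data, m0a, a, tr_ms, b1a))
  allsig <- unlist(lapply(clean, as.vector))
  sigma <- noise_sd * stats::median(allsig[allsig > 0])
  vols <- lapply(seq_along(flip_angles_deg), function(k) {
    s <- clean[[k]]
    if (noise_sd > 0 && noise_model == "rician") {
      s <- sqrt((s + stats::rnorm(length(s), 0, sigma))^2 +
                  stats::rnorm(length(s), 0, sigma)^2)
    } else if (noise_sd > 0 && noise_model == "gaussian") {
      s <- s + stats::rnorm(length(s), 0, sigma)
    }
    mri_volume(array(s, dim = dm), affine = t1_truth$affine)
  })
  vfa_series(vols, flip_angles_deg, tr_ms)
}

#' Generate and write a phantom cohort
#'
#' One subdirectory per patient with the pre/post T1 maps (or raw VFA
#' series when `write_vfa = TRUE`) and the liver mask as NIfTI, a cohort
#' CSV of patient records, and a JSON manifest listing every path and seed.
#' Group sizes follow the requested counts; per-group uptake calibration
#' makes group-mean reduction rates decrease with severity.
#'
#' @param n_per_group named counts, e.g. `c(normal = 132, impaired = 59,
#'   severe = 4)`; missing groups count 0.
#' @param spec a [phantom_spec()]; per-patient seeds are derived from
#'   `spec$seed`.
#' @param out_dir output directory (created if needed).
#' @param write_vfa also write the raw two-angle series per phase.
#' @param noise_model forwarded to [synthesize_vfa()] when writing VFA.
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
make_cohort <- function(n_per_group, spec = phantom_spec(), out_dir,
                        write_vfa = FALSE, noise_model = "rician") {
  groups <- c("normal", "impaired", "severe")
  counts <- stats::setNames(rep(0L, 3), groups)
  counts[names(n_per_group)] <- as.integer(n_per_group)
  if (any(counts < 0)) stop("make_cohort: counts must be >= 0")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("make_cohort: cannot create ", out_dir)

  sampled <- cohort_records(counts, spec$seed)
  n_pat <- length(sampled$records)
  records <- list()
  entries <- list()
  for (idx in seq_len(n_pat)) {
      pat <- sampled$records[[idx]]
      g <- pat$meld_group
      pseed <- sampled$seeds[idx]
      pspec <- spec
      pspec$seed <- pseed
      gt <- make_ground_truth(pspec, pat)
      pdir <- file.path(out_dir, pat$id)
      dir.create(pdir, showWarnings = FALSE)
      paths <- list(
        t1_pre = file.path(pdir, "t1_pre.nii.gz"),
        t1_post = file.path(pdir, "t1_post.nii.gz"),
        mask = file.path(pdir, "mask.nii.gz")
      )
      write_nifti(gt$t1_pre, paths$t1_pre)
      write_nifti(gt$t1_post, paths$t1_post)
      write_nifti(gt$mask, paths$mask, datatype = "uint8")
      if (write_vfa) {
        for (phase in c("pre", "post")) {
          tv <- if (phase == "pre") gt$t1_pre else gt$t1_post
          ser <- synthesize_vfa(tv, gt$m0, c(2, 15), 5,
                                noise_sd = spec$noise_sd, seed = pseed + 7L,
                                noise_model = noise_model)
          for (ai in seq_along(ser$flip_angles_deg)) {
            p <- file.path(pdir, sprintf("vfa_%s_fa%02d.nii.gz", phase,
                                         ser$flip_angles_deg[ai]))
            write_nifti(ser$volumes[[ai]], p)
            paths[[sprintf("vfa_%s_fa%02d", phase, ser$flip_angles_deg[ai])]] <- p
          }
        }
      }
      records[[idx]] <- pat
      entries[[idx]] <- c(list(id = pat$id, group = g, seed = pseed,
                               true_uptake_mean = mean(gt$uptake$data[gt$mask$data > 0.5])),
                          lapply(paths, as.character))
  }
  csv_path <- file.path(out_dir, "cohort.csv")
  if (n_pat > 0) {
    utils::write.csv(do.call(rbind, records), csv_path, row.names = FALSE)
  } else {
    utils::write.csv(data.frame(), csv_path, row.names = FALSE)
  }
  manifest <- list(
    n_patients = n_pat,
    counts = as.list(counts),
    spec = unclass(spec),
    cohort_csv = csv_path,
    vfa = write_vfa,
    patients = entries
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}


# Sample all patient records for a cohort, enforcing the generator's
# group-calibration contract: the realized group means of the target
# uptake must be strictly ordered normal > impaired > severe (groups with
# no patients are ignored). Tiny groups (the reference cohort has n = 4
# severe patients) can violate the ordering by sampling luck, so offending
# groups' uptake draws are rejection-resampled (bounded at 200 attempts),
# mirroring how each patient's labs are rejection-sampled into the MELD
# band.
cohort_records <- function(counts, base_seed) {
  groups <- c("normal", "impaired", "severe")
  pats <- list()
  idx <- 0L
  seeds <- integer(0)
  for (g in groups) {
    for (k in seq_len(counts[[g]])) {
      idx <- idx + 1L
      pseed <- (base_seed * 10007L + idx * 131L) %% .Machine$integer.max
      pats[[idx]] <- make_patient(g, seed = pseed, id = sprintf("P%03d", idx))
      seeds[idx] <- pseed
    }
  }
  if (!idx) return(list(records = pats, seeds = seeds))
  grp_of <- vapply(pats, function(p) p$meld_group, "")
  group_mean <- function(g) {
    sel <- grp_of == g
    if (!any(sel)) return(NULL)
    mean(vapply(pats[sel], function(p) p$target_uptake, 0))
  }
  ordered_ok <- function() {
    mm <- Filter(Negate(is.null),
                 lapply(groups, group_mean))
    length(mm) < 2 || all(diff(unlist(mm)) < 0)
  }
  attempt <- 0L
  while (!ordered_ok()) {
    attempt <- attempt + 1L
    if (attempt > 200L)
      stop("cohort_records: could not realize severity-ordered group uptake means")
    # resample the uptake draws of the smallest non-conforming group
    mm <- unlist(Filter(Negate(is.null), lapply(groups, group_mean)))
    present <- groups[groups %in% grp_of]
    bad <- present[which(diff(mm) >= 0) + 1]
    gfix <- bad[which.min(table(factor(grp_of, groups))[bad])]
    cal <- PHANTOM_UPTAKE_CALIBRATION[[gfix]]
    local_rng((base_seed + 7919L * attempt) %% .Machine$integer.max)
    for (i in which(grp_of == gfix))
      pats[[i]]$target_uptake <-
        clamp(stats::rnorm(1, cal["mean"], cal["sd"]), 0.02, 0.93)
  }
  list(records = pats, seeds = seeds)
}

# --- small shared helpers ----------------------------------------------

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Seed the RNG for the calling scope and restore the previous state when
# that scope exits, so package functions never clobber the user's RNG.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed) %% .Machine$integer.max,
                    .local_envir = envir)
  invisible(seed)
}

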