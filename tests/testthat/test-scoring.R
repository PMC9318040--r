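vol_of <- function(arr, spacing = c(1, 1, 1)) mri_volume(arr, spacing = spacing)

test_that("rr_map implements the reduction-rate formula with exclusions", {
  dm <- c(4, 4, 4)
  pre <- vol_of(array(1000, dm))
  post <- vol_of(array(400, dm))
  mask <- vol_of(array(1, dm))
  rr <- rr_map(pre, post, mask)
  expect_true(all(rr$data == 60))
  expect_equal(attr(rr, "n_used"), 64L)
  expect_equal(attr(rr, "n_excluded"), 0L)
  # identity: post == pre -> 0 everywhere
  rr0 <- rr_map(pre, pre, mask)
  expect_true(all(rr0$data == 0))
  # invalid pre / nonpositive pre / invalid post are excluded and counted
  pre2 <- pre; pre2$data[1, 1, 1] <- NA; pre2$data[2, 1, 1] <- 0
  post2 <- post; post2$data[3, 1, 1] <- NA
  rr2 <- rr_map(pre2, post2, mask)
  expect_equal(attr(rr2, "n_excluded"), 3L)
  expect_equal(attr(rr2, "n_used") + attr(rr2, "n_excluded"), sum(mask$data))
  # negative rates retained, clipping counted
  post3 <- post; post3$data[1, 2, 1] <- 1500; post3$data[2, 2, 1] <- 5000
  rr3 <- rr_map(pre, post3, mask)
  expect_equal(rr3$data[1, 2, 1], -50)
  expect_equal(rr3$data[2, 2, 1], -100)   # clipped at -100
  expect_equal(attr(rr3, "n_clipped"), 1L)
  # errors
  expect_error(rr_map(pre, post, vol_of(array(0, dm))), "empty")
  expect_error(rr_map(pre, vol_of(array(400, dm), spacing = c(2, 2, 2)), mask),
               "geometry")
})

test_that("rr_map equals an explicit per-voxel loop bit-exactly", {
  gt <- ph_nodef()
  mask <- gt$mask
  rr <- rr_map(gt$t1_pre, gt$t1_post, mask)
  dm <- dim(mask$data)
  oracle <- array(NA_real_, dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (mask$data[i, j, k] > 0.5) {
      p <- gt$t1_pre$data[i, j, k]
      q <- gt$t1_post$data[i, j, k]
      if (!is.na(p) && !is.na(q) && p > 0) {
        v <- (p - q) / p * 100
        oracle[i, j, k] <- max(-100, min(100, v))
      }
    }
  }
  expect_identical(rr$data, oracle)
})

test_that("rr map reproduces the phantom uptake field within 1 point", {
  gt <- ph_nodef()
  rr <- rr_map(gt$t1_pre, gt$t1_post, gt$mask)
  m <- mask_lgl(gt)
  expect_lt(mean(abs(rr$data[m] - 100 * gt$uptake$data[m])), 1)
})

test_that("rrt1_liver: uniform-field arithmetic in both conventions", {
  # a uniform 50% map already on the standard grid
  dm <- c(10, 10, 10)
  sp <- rep(MELIF_STANDARD_GRID_MM, 3)
  rr <- vol_of(array(50, dm), spacing = sp)
  mask <- vol_of(array(1, dm), spacing = sp)
  expect_equal(rrt1_liver(rr, mask, "mean_pct"), 50)
  integ <- rrt1_liver(rr, mask, "integrated")
  # 0.5 per standard-grid voxel; resampled count within a voxel-rounding
  # margin of the original 1000
  expect_equal(integ / 0.5, 1000, tolerance = 0.05)
  # intensive vs additive: two disjoint identical livers
  dm2 <- c(22, 10, 10)
  rr2d <- array(50, dm2)
  mk2 <- array(0, dm2)
  mk2[1:10, , ] <- 1; mk2[13:22, , ] <- 1
  rr2 <- vol_of(rr2d, spacing = sp)
  mask2 <- vol_of(mk2, spacing = sp)
  expect_equal(rrt1_liver(rr2, mask2, "mean_pct"), 50)
  expect_equal(rrt1_liver(rr2, mask2, "integrated") / integ, 2,
               tolerance = 0.05)
  expect_error(rrt1_liver(vol_of(array(NA_real_, dm), spacing = sp), mask),
               "valid")
})

test_that("patient_factor matches hand evaluation and scales as a power law", {
  expect_equal(patient_factor(1.7, 83, 1513), 4.515e-3, tolerance = 1e-4)
  expect_equal(patient_factor(1, 1, 1), 1)
  f0 <- patient_factor(1.8, 90, 1500)
  expect_equal(patient_factor(1.8, 90, 3 * 1500) / f0, 3^-0.6)
  expect_equal(patient_factor(1.8, 4 * 90, 1500) / f0, 4^-0.3)
  expect_error(patient_factor(0, 80, 1500), "positive")
})

test_that("melif_score is the plain scaled product", {
  expect_equal(melif_score(0.0045, 0), 0)
  expect_equal(melif_score(0.0045, 16000), 0.694 * 0.0045 * 16000)
  expect_equal(melif_score(0.0045, 16000, c_scale = 2 * MELIF_C),
               2 * melif_score(0.0045, 16000))
  expect_error(melif_score(NA, 1), "finite")
})

test_that("MELD follows the UNOS clamping, cap and rounding rules", {
  expect_equal(meld(1, 1, 1, FALSE), 6L)
  expect_equal(meld(2.0, 1.5, 1.2, FALSE), 15L)
  # creatinine cap at 4.0, and dialysis override
  expect_equal(meld(1, 1, 9, FALSE), meld(1, 1, 4, FALSE))
  expect_equal(meld(1, 1, 1.2, TRUE), meld(1, 1, 4, FALSE))
  # sub-1.0 labs are raised to 1.0
  expect_equal(meld(0.4, 0.9, 0.7, FALSE), 6L)
  # weak monotonicity in each lab
  base <- meld(2, 1.5, 1.2)
  expect_gte(meld(3, 1.5, 1.2), base)
  expect_gte(meld(2, 1.9, 1.2), base)
  expect_gte(meld(2, 1.5, 2.0), base)
  expect_error(meld(-1, 1, 1), "positive")
})

test_that("MELD grouping uses the 10/18 boundaries", {
  expect_equal(as.character(meld_group(c(6, 10, 11, 18, 19, 30))),
               c("normal", "normal", "impaired", "impaired",
                 "severe", "severe"))
  expect_error(meld_group(5), "start at 6")
})

test_that("mean-patient uniform 50% phantom scores MELIF near 51", {
  # Table-1 anthropometrics, uniform half reduction, standard grid: the
  # scale anchor of the integrated convention
  pat <- list(height_m = 1.7, weight_kg = 83, liver_volume_ml = 1513,
              bilirubin_mg_dl = 1, inr = 1, creatinine_mg_dl = 1,
              dialysis = FALSE)
  gt <- make_ground_truth(phantom_spec(seed = 301, uptake_mean = 0.5,
                                       uptake_sd = 0,
                                       deformation_amplitude_mm = 0),
                          as.data.frame(c(pat, list(target_uptake = 0.5))))
  res <- score_patient(gt$t1_pre, gt$t1_post, gt$mask, pat)
  expect_equal(res$melif, 51, tolerance = 0.10)
  expect_equal(res$rrt1_mean_pct, 50, tolerance = 0.03)
  expect_equal(res$meld, 6L)
  expect_equal(res$meld_group, "normal")
  # invariant: melif = c * f_p * integrated, exactly
  expect_equal(res$melif, MELIF_C * res$f_p * res$rrt1_integrated)
  # exclusion accounting
  expect_equal(res$n_voxels_used + res$n_voxels_excluded,
               sum(gt$mask$data > 0.5))
})

test_that("MELIF is invariant to acquisition resolution within 2%", {
  pat <- list(height_m = 1.7, weight_kg = 83, liver_volume_ml = 1200,
              bilirubin_mg_dl = 1, inr = 1, creatinine_mg_dl = 1,
              dialysis = FALSE, target_uptake = 0.5)
  score_at <- function(spacing, shape) {
    gt <- make_ground_truth(phantom_spec(seed = 302, uptake_mean = 0.5,
                                         grid_shape = shape,
                                         voxel_spacing_mm = rep(spacing, 3),
                                         deformation_amplitude_mm = 0),
                            as.data.frame(pat))
    score_patient(gt$t1_pre, gt$t1_post, gt$mask, pat)$melif
  }
  m2 <- score_at(2.5, c(84, 76, 64))
  m4 <- score_at(4, c(56, 48, 40))
  expect_lt(abs(m2 - m4) / m4, 0.02)
})

test_that("raising uptake raises both conventions and MELIF", {
  pat <- list(height_m = 1.7, weight_kg = 83, liver_volume_ml = 1400,
              bilirubin_mg_dl = 1, inr = 1, creatinine_mg_dl = 1,
              dialysis = FALSE)
  vals <- lapply(c(0.2, 0.4, 0.6), function(u) {
    gt <- make_ground_truth(phantom_spec(seed = 303, uptake_mean = u,
                                         deformation_amplitude_mm = 0),
                            as.data.frame(c(pat, list(target_uptake = u))))
    score_patient(gt$t1_pre, gt$t1_post, gt$mask, pat)
  })
  expect_true(all(diff(vapply(vals, `[[`, 0, "rrt1_mean_pct")) > 0))
  expect_true(all(diff(vapply(vals, `[[`, 0, "rrt1_integrated")) > 0))
  expect_true(all(diff(vapply(vals, `[[`, 0, "melif")) > 0))
})
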