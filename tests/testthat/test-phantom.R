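test_that("make_patient lands in the requested MELD band deterministically", {
  for (seed in 1:6) {
    expect_lte(make_patient("normal", seed = seed)$meld, 10)
    mi <- make_patient("impaired", seed = seed)$meld
    expect_true(mi >= 11 && mi <= 18)
    expect_gt(make_patient("severe", seed = seed)$meld, 18)
  }
  expect_identical(make_patient("impaired", seed = 42),
                   make_patient("impaired", seed = 42))
  # anthropometrics centred on the reference cohort
  hw <- vapply(1:60, function(s) {
    p <- make_patient("normal", seed = s)
    c(p$height_m, p$weight_kg, p$liver_volume_ml)
  }, numeric(3))
  expect_equal(mean(hw[1, ]), 1.70, tolerance = 0.05)
  expect_equal(mean(hw[2, ]), 83, tolerance = 0.1)
  expect_equal(mean(hw[3, ]), 1540, tolerance = 0.15)
})

test_that("ground truth respects volume, uptake mean and deformation bound", {
  gt <- ph_nodef()
  pat <- gt$patient
  m <- mask_lgl(gt)
  # mask volume within 2% of the requested liver volume
  expect_lt(abs(mask_volume_ml(gt$mask) - pat$liver_volume_ml) /
              pat$liver_volume_ml, 0.02)
  # voxel-mean fractional reduction within 0.02 of the requested uptake
  rr_frac <- (gt$t1_pre$data[m] - gt$t1_post$data[m]) / gt$t1_pre$data[m]
  expect_lt(abs(mean(rr_frac) - pat$target_uptake), 0.02)
  # t1_post <= t1_pre wherever uptake > 0 (zero-deformation phantom)
  up <- gt$uptake$data[m] > 0
  expect_true(all(gt$t1_post$data[m][up] <= gt$t1_pre$data[m][up] + 1e-9))
  # deformation bounded by the requested amplitude, and attained
  gtd <- ph_def()
  mag <- deformation_magnitude(gtd$deformation)$data
  expect_lte(max(mag), 5 + 1e-9)
  expect_gt(max(mag), 4.99)
})

test_that("zero uptake makes the post map the deformed pre map", {
  pat <- make_patient("normal", seed = 104)
  pat$target_uptake <- 0
  gt <- make_ground_truth(phantom_spec(seed = 104, uptake_mean = 0,
                                       uptake_sd = 0,
                                       deformation_amplitude_mm = 0), pat)
  expect_equal(gt$t1_post$data, gt$t1_pre$data)
  expect_true(all(gt$uptake$data == 0))
})

test_that("identical spec and seed give bit-identical phantoms", {
  pat <- make_patient("impaired", seed = 105)
  a <- make_ground_truth(phantom_spec(seed = 105), pat)
  b <- make_ground_truth(phantom_spec(seed = 105), pat)
  expect_identical(a$t1_pre$data, b$t1_pre$data)
  expect_identical(a$t1_post$data, b$t1_post$data)
  expect_identical(a$deformation$dx_vol$data, b$deformation$dx_vol$data)
})

test_that("synthesize_vfa implements the SPGR forward model", {
  # closed-form check at one voxel
  t1 <- mri_volume(array(600, c(2, 2, 2)))
  ser <- synthesize_vfa(t1, m0 = 1000, flip_angles_deg = c(2, 15), tr_ms = 5,
                        noise_sd = 0, noise_model = "none")
  for (k in 1:2) {
    a <- c(2, 15)[k] * pi / 180
    e1 <- exp(-5 / 600)
    expect_equal(ser$volumes[[k]]$data[1, 1, 1],
                 1000 * sin(a) * (1 - e1) / (1 - e1 * cos(a)))
  }
  # T1 -> infinity limit: signal -> 0
  tinf <- mri_volume(array(1e12, c(2, 2, 2)))
  sinf <- synthesize_vfa(tinf, 1000, c(2, 15), 5, noise_sd = 0,
                         noise_model = "none")
  expect_lt(max(sinf$volumes[[2]]$data), 1e-6)
  # configuration errors
  expect_error(synthesize_vfa(t1, 1000, c(5, 5), 5), "distinct")
  expect_error(synthesize_vfa(t1, 1000, c(2, 15), 0), "positive")
  # Rician magnitudes are nonnegative
  sn <- synthesize_vfa(t1, 1000, c(2, 15), 5, noise_sd = 0.05, seed = 3)
  expect_true(all(sn$volumes[[1]]$data >= 0))
})

test_that("make_cohort writes the promised files and group structure", {
  out <- file.path(tempdir(), "cohort_small")
  unlink(out, recursive = TRUE)
  spec <- phantom_spec(seed = 9, deformation_amplitude_mm = 0)
  man <- make_cohort(c(normal = 2, impaired = 1), spec, out)
  expect_equal(man$n_patients, 3)
  expect_length(list.dirs(out, recursive = FALSE), 3)
  csv <- read.csv(file.path(out, "cohort.csv"))
  expect_equal(nrow(csv), 3)
  expect_equal(sum(csv$meld_group == "normal"), 2)
  expect_true(all(file.exists(vapply(man$patients,
                                     function(p) p$t1_pre, ""))))
  expect_true(file.exists(file.path(out, "manifest.json")))
  # empty counts: empty manifest, no error
  out0 <- file.path(tempdir(), "cohort_empty")
  man0 <- make_cohort(c(normal = 0), spec, out0)
  expect_equal(man0$n_patients, 0)
})

test_that("group-calibrated uptake decreases with severity", {
  # oracle: recompute the generated uptake-field means per group
  spec <- phantom_spec(seed = 77, deformation_amplitude_mm = 0)
  mean_uptake <- function(grp, n) {
    mean(vapply(seq_len(n), function(k) {
      pat <- make_patient(grp, seed = 77 + 13 * k)
      gt <- make_ground_truth(spec, pat)
      mean(gt$uptake$data[mask_lgl(gt)])
    }, 0))
  }
  u_n <- mean_uptake("normal", 6)
  u_i <- mean_uptake("impaired", 6)
  u_s <- mean_uptake("severe", 6)
  expect_gt(u_n, u_i)
  expect_gt(u_i, u_s)
})
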