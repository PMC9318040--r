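test_that("mri_volume validates input and reports geometry", {
  v <- mri_volume(array(1:8, c(2, 2, 2)), spacing = c(1, 2, 3),
                  origin = c(-1, 0, 4))
  expect_equal(vol_spacing(v), c(1, 2, 3))
  expect_equal(voxel_volume_mm3(v), 6)
  expect_error(mri_volume(matrix(1, 2, 2)), "3-D")
  expect_error(mri_volume(array(1, c(2, 2, 2)), spacing = c(0, 1, 1)),
               "positive")
})

test_that("voxel/world mappings are mutually inverse", {
  v <- mri_volume(array(0, c(4, 5, 6)), spacing = c(2, 3, 1.5),
                  origin = c(-10, 5, 2))
  idx <- rbind(c(0, 0, 0), c(3, 4, 5), c(1.5, 2.25, 0.5))
  w <- melif:::voxel_to_world(v, idx)
  expect_equal(w[1, ], c(-10, 5, 2))
  expect_equal(melif:::world_to_voxel(v, w), idx)
  # general (rotated) affine path agrees with the fast axis-aligned path
  th <- 0.3
  aff <- diag(4)
  aff[1:2, 1:2] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  vr <- mri_volume(array(0, c(4, 5, 6)), affine = aff)
  wr <- melif:::voxel_to_world(vr, idx)
  expect_equal(melif:::world_to_voxel(vr, wr), idx, tolerance = 1e-12)
})

test_that("resample_to: identity, constant invariance, down/up error bound", {
  gt <- ph_nodef()
  t1 <- gt$t1_pre
  # identical geometry: values unchanged
  same <- resample_to(t1, geometry_of(t1))
  expect_identical(same$data, t1$data)
  # constant map stays constant under linear interpolation on any grid
  cv <- mri_volume(array(7.5, dim(t1$data)), affine = t1$affine)
  g2 <- vol_geometry(c(20, 18, 16), spacing = c(5.5, 6, 7),
                     origin = c(-50, -48, -40))
  cr <- resample_to(cv, g2, "linear")
  expect_true(all(abs(cr$data[!is.na(cr$data)] - 7.5) < 1e-9))
  # downsample 2x then upsample back: smooth map, MAD below 1% of range
  g_half <- melif:::downsample_geom(t1, 2)
  down <- resample_to(t1, g_half, "linear")
  back <- resample_to(down, geometry_of(t1), "linear")
  ok <- !is.na(back$data)
  mad <- mean(abs(back$data[ok] - t1$data[ok]))
  expect_lt(mad, 0.01 * diff(range(t1$data)))
})

test_that("out-of-field samples are invalid and NA propagates", {
  v <- mri_volume(array(1:27, c(3, 3, 3)))
  expect_true(is.na(sample_world(v, matrix(c(-5, 0, 0), 1))))
  v$data[2, 2, 2] <- NA
  # linear interpolation touching the NA corner is invalid
  expect_true(is.na(sample_world(v, matrix(c(1.5, 1.5, 1.5), 1))))
  # nearest-neighbour at a point rounding away from the NA voxel is valid
  expect_equal(sample_world(v, matrix(c(0.4, 1, 1), 1), "nearest"),
               v$data[1, 2, 2])
})

test_that("NIfTI round trip preserves data, affine and NA voxels", {
  gt <- ph_nodef()
  t1 <- gt$t1_pre
  t1$data[1, 1, 1] <- NA
  tf <- file.path(tempdir(), "rt.nii.gz")
  write_nifti(t1, tf)
  back <- read_nifti(tf)
  expect_true(same_geometry(back, t1))
  expect_true(is.na(back$data[1, 1, 1]))
  ok <- !is.na(t1$data)
  # float32 storage: relative error at single precision
  expect_lt(max(abs(back$data[ok] - t1$data[ok]) / pmax(1, abs(t1$data[ok]))),
            1e-6)
  # uncompressed path and integer datatype
  tf2 <- file.path(tempdir(), "rt_mask.nii")
  write_nifti(gt$mask, tf2, datatype = "uint8")
  mback <- read_nifti(tf2)
  expect_identical(mback$data, gt$mask$data)
  # 4-D displacement field round trip
  tf3 <- file.path(tempdir(), "field.nii.gz")
  f <- gt$deformation
  write_nifti(list(f$dx_vol, f$dy_vol, f$dz_vol), tf3)
  comps <- read_nifti(tf3)
  expect_length(comps, 3)
  expect_equal(comps[[2]]$data, f$dy_vol$data, tolerance = 1e-6)
})

test_that("NIfTI output is readable by an independent implementation", {
  # nibabel (pre-installed with the environment's Python) as external oracle
  py <- Sys.which("python")
  expect_true(nzchar(py))
  gt <- ph_nodef()
  tf <- file.path(tempdir(), "oracle.nii.gz")
  write_nifti(gt$t1_pre, tf)
  script <- sprintf(
    "import nibabel, json; v = nibabel.load(%s); d = v.get_fdata(); print(json.dumps({'shape': list(v.shape), 'sum': float(d.sum()), 'a00': float(v.affine[0,0]), 'a03': float(v.affine[0,3])}))",
    deparse(tf))
  out <- system2(py, c("-c", shQuote(script)), stdout = TRUE)
  res <- jsonlite::fromJSON(out[length(out)])
  expect_equal(unlist(res$shape), dim(gt$t1_pre$data))
  expect_equal(res$sum, sum(gt$t1_pre$data), tolerance = 1e-6)
  expect_equal(res$a00, gt$t1_pre$affine[1, 1])
  expect_equal(res$a03, gt$t1_pre$affine[1, 4])
})
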