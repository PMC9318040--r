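# Shared phantom fixtures, built once per test run and memoised. All
# fixtures are generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, builder) {
  if (!exists(key, .fixture_env)) assign(key, builder(), .fixture_env)
  get(key, .fixture_env)
}

# default-grid phantom without inter-phase deformation: exact rr truth
ph_nodef <- function() fixture("ph_nodef", function() {
  pat <- make_patient("normal", seed = 101)
  make_ground_truth(phantom_spec(seed = 101, deformation_amplitude_mm = 0), pat)
})

# default-grid phantom with the default 5 mm deformation
ph_def <- function() fixture("ph_def", function() {
  pat <- make_patient("normal", seed = 102)
  make_ground_truth(phantom_spec(seed = 102), pat)
})

# band-limited 2.5 mm phantom for registration validation (see vignette:
# zero uptake so pre/post mismatch is purely geometric, blur at 1.8 voxels
# so the mismatch measure is not interpolation-limited, and a bulk
# inter-phase shift on top of the 5 mm smooth deformation, as between real
# native and hepatobiliary acquisitions)
ph_reg <- function() fixture("ph_reg", function() {
  pat <- make_patient("normal", seed = 103)
  pat$liver_volume_ml <- 700
  pat$target_uptake <- 0
  spec <- phantom_spec(seed = 103, grid_shape = c(72, 64, 56),
                       voxel_spacing_mm = rep(2.5, 3),
                       uptake_mean = 0, uptake_sd = 0, blur_vox = 1.8,
                       bulk_shift_mm = c(4, -3, 2))
  make_ground_truth(spec, pat)
})

mask_lgl <- function(gt) gt$mask$data > 0.5
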