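---
title: "Methods: liver-function scoring from paired T1 maps, and the phantom that validates it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: liver-function scoring from paired T1 maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

Gadoxetic acid is transported into functioning hepatocytes, where it
shortens the T1 relaxation time; about twenty minutes after injection
(the hepatobiliary phase) the intracellular concentration — and hence the
T1 shortening — reflects regional hepatocyte function. `melif` operates on
quantitative T1 maps of the native and hepatobiliary phases and derives:

1. **Voxel reduction rate** `rrT1 = (T1_pre − T1_post_reg)/T1_pre × 100` (%),
   computed after registering the post-contrast map onto the pre-contrast
   grid so that numerator and denominator refer to the same tissue point.
   Negative values (paradoxical enhancement, registration or fit
   artifacts) are retained rather than floored, and values are clipped to
   [−100, 100] with clip counts reported; voxels with invalid or
   non-positive `T1_pre`, or invalid registered `T1_post`, are excluded
   and counted. Exclusion accounting is an invariant:
   `n_used + n_excluded` always equals the masked voxel count.

2. **Whole-liver aggregation** in two deliberately distinct conventions.
   The *voxel mean* (`mean_pct`) is intensive — independent of liver
   size — and is the quantity tabulated as "rrT1_liver (%)". The
   *integrated* form sums the fractional reduction over the liver and is
   extensive: it grows with functional liver volume. A literal voxel sum
   would depend on acquisition resolution (halving the voxel size would
   octuple it), so the sum is always evaluated on a fixed **standard
   scoring grid**, 3.6 mm isotropic by default (about 46.7 mm³ per
   voxel). With that spacing, an average liver (1513 mL) at a uniform 50%
   reduction and average anthropometrics lands at MELIF ≈ 51, i.e. on the
   intended 20–80 score scale; the spacing is configurable (`grid_mm`)
   and the score is invariant to acquisition resolution within 2% (a
   tested property). Resampling onto the standard grid uses normalized
   (validity-weighted) interpolation: ordinary linear resampling would
   invalidate every boundary voxel whose stencil touches the outside of
   the liver and systematically erode the surface from the integral (a
   ~13% bias at 4 mm acquisition resolution when we measured it).

3. **Patient factor and MELIF.**
   `f_p = height^0.6 / (weight^0.3 · volume^0.6)` with units fixed as
   metres, kilogrammes and millilitres — the only unit convention that,
   combined with the standard grid, reproduces the published score scale.
   `MELIF = c · f_p · rrT1_integrated` with `c = 0.694` kept as a fixed
   constant; the 20–80 band is a cohort-level property of `c`, checked
   statistically, never enforced per patient.

4. **MELD reference.** UNOS-style: labs below 1.0 raised to 1.0,
   creatinine capped at 4.0 mg/dL (and forced to 4.0 under dialysis),
   `round(10(0.957 ln creat + 0.378 ln bili + 1.120 ln INR + 0.643))`,
   floored at 6. Groups: ≤ 10 normal, 11–18 impaired, > 18 severe.

## T1 fitting

T1 maps are fitted from variable-flip-angle spoiled gradient-echo series
by the linearized DESPOT1 estimator: `S/sin α` regressed on `S/tan α`
gives slope `E1 = exp(−TR/T1)` and intercept `M0(1 − E1)`. We chose the
linearized (closed-form) fit over nonlinear least squares because it is
the field's standard two-angle estimator, exact in the noiseless case
(tested to 0.1% over 100–3000 ms) and fast enough to run per voxel in
plain R. B1 transmit inhomogeneity is corrected by scaling the nominal
angles with a user-supplied relative-B1 map; estimating B1 itself is out
of scope. Fits with slope outside (0, 1), all-zero signal, or T1 outside
the physiological window [1, 5000] ms are flagged invalid rather than
clipped — downstream stages treat invalidity explicitly. Default angles
(2°/15°) and TR (5 ms) are configurable conventions, not asserted
properties of any particular scanner protocol.

## Registration

The post-contrast map is aligned onto the pre-contrast map by classical
multi-resolution machinery, implemented in the package because the R
environment offers no ITK-grade toolkit:

* **Rigid stage** — a translation grid pre-search (±16 mm, 4 mm lattice)
  followed by Nelder-Mead over 6 parameters, by default on normalized
  mutual information, which tolerates the contrast-induced intensity
  change between phases. Recovers a pure 10 mm translation to ≈ 0.02 mm.
* **Deformable stage** — a Gaussian-regularized free-form refinement with
  demons-style intensity forces on a 3-level pyramid. Before each force
  evaluation the warped moving image is passed through a
  *conditional-mean intensity remapping* (each moving intensity replaced
  by the mean fixed intensity observed at similar moving intensities):
  any difference explainable by a global transfer function — including
  the regional uptake pattern, which has no counterpart in the
  pre-contrast image — is flattened, so forces are driven by structural
  mismatch only. Updates are capped at 0.8 voxels per iteration and the
  field is smoothed (σ = 2 voxels) each step; iteration stops when the
  metric stalls, and a monotonically worsening metric raises a
  registration error with the metric trace attached.

The procedure is fully deterministic (fixed-stride sampling, no
stochastic metric estimation), so repeated runs return identical fields —
the `seed` argument exists only for interface stability.

Why not B-spline control points with Mattes mutual information, the more
common published recipe? Without analytic gradients (and without compiled
optimization infrastructure) a control-point MI optimization is orders of
magnitude slower in R; the regularized demons refinement satisfies the
same contract — voxel-level correspondence, deterministic, divergence
detection — at tractable cost, and its accuracy is validated against the
phantom's known fields rather than assumed.

## The phantom: what its world is, and what a green test establishes

Every claim in the test suite is made against synthetic data whose ground
truth is known analytically. The stated world:

* **Patients.** Height 1.70 ± 0.08 m, weight 83 ± 16 kg, age 62 ± 11,
  79% male; liver volume 1513 ± 415 mL with a severity shift (centres
  1540/1460/1250 mL). MELD labs are log-normal around clinically
  plausible centres per group and rejection-sampled (bounded at 1000
  attempts) until the computed MELD lands in the requested band — group
  membership is guaranteed by construction, not by luck.
* **Uptake.** Post-contrast truth is `T1_post = T1_pre × (1 − u)` with
  `u` a Gaussian-correlated random field (FWHM 30 mm, SD 0.08 as the
  default regional heterogeneity) whose liver mean is renormalized to the
  target exactly. This makes the voxel reduction rate equal `100 u`
  identically — the analytic oracle for the scoring chain. Group
  calibration of the mean (0.54 / 0.43 / 0.31 with SDs 0.10/0.12/0.14)
  reproduces the reference per-group score summaries. Because the
  severe group of the reference cohort has only four members, its sample
  mean is volatile; cohort generation rejection-resamples a
  non-conforming group's uptake draws (bounded at 200 attempts) so the
  realized group means are severity-ordered — the generator's contract,
  enforced the same way as the per-patient MELD bands.
* **Anatomy.** A two-ellipsoid union binary-searched to the requested
  volume within 0.5%; a spleen-like bright distractor exercises the
  largest-component rule of the phantom segmenter; ~5% of the liver is
  vessel-like blood pool with no hepatocyte uptake. The vessels are not
  decoration: the uptake texture itself is *unmatchable* between phases,
  so contrast-stable structure is what makes deformable registration
  well-posed — exactly as in real hepatobiliary imaging, where vessels
  remain hypointense against enhancing parenchyma.
* **Geometry.** A smooth random displacement field (correlation length
  ≥ 6× the amplitude, so the map stays invertible), max magnitude equal
  to `deformation_amplitude_mm` (default 5 mm), optionally composed with
  a bulk inter-phase translation (`bulk_shift_mm`, default 0) emulating
  patient repositioning between acquisitions. The stored field maps
  post-grid points to pre-grid points; the post map is rendered through
  the field's fixed-point inverse, so applying the stored field to the
  post map recovers the undeformed truth up to interpolation error.
* **Signal.** SPGR magnitudes from the signal equation, Rician noise
  (Gaussian or none for linear-regime tests) with σ defined relative to
  the median noiseless signal, i.e. `noise_sd = 1/SNR`; default 0.02. A
  mild partial-volume band limit (`blur_vox`, default σ = 1 voxel) is
  applied to the pre map *before* the post map is composed, so the
  analytic rr identity is preserved exactly.

What the phantom does **not** emulate: real vascular trees or lesions,
k-space/reconstruction artifacts, motion ghosting, fat–water effects,
field-strength-dependent relaxivity (field strength is metadata only),
and any correlation structure between labs and imaging beyond the group
calibration. A green cohort test therefore establishes that the *pipeline
arithmetic and statistics* behave as specified under the stated world —
it says nothing about biological validity on real patients.

### The registration validation world

Registration accuracy is measured on a dedicated phantom: 2.5 mm
isotropic voxels, zero uptake, band limit σ = 1.8 voxels, and a 5 mm
smooth deformation composed with a (4, −3, 2) mm bulk shift. Three
choices need justification:

* *Zero uptake*, because with uptake present the pre/post difference is
  physically irreducible and "mismatch reduction" is ill-defined.
* *Stronger band limit*, because the reduction measure compares
  resampled images: below the band limit the measure is dominated by
  interpolation error, not alignment. We measured the ceiling — the
  reduction achieved by warping with the *true* field — at ~63–72% for
  σ = 1 voxel and 86–93% for σ = 1.8; a criterion of ≥ 80% is only
  meaningful in the band-limited regime.
* *Bulk shift*, because a max-normalized smooth field can happen to be
  small inside the liver (one probed seed gave a mask-mean of 1.6 mm,
  with a truth-field ceiling of 76.6% — perfect recovery would fail the
  criterion). Real phase pairs always carry bulk repositioning; including
  it makes the baseline mismatch dominated by recoverable geometry. With
  it, measured reductions were 83–92% across probed seeds and the mean
  residual field error 0.9–1.6 mm (voxel 2.5 mm).

## Statistics

* Descriptive summaries use the (n+1)p percentile convention (R type 6)
  for quartiles — matching the desktop statistics package whose report
  format the battery emulates — with Tukey whiskers at 1.5 IQR and
  outliers listed.
* Normality: the D'Agostino–Pearson omnibus K² (D'Agostino skewness z +
  Anscombe–Glynn kurtosis z, χ² with 2 df), verified to 10 decimal places
  against an independent implementation. Below n = 8 the result is a
  typed "not assessable", mirroring how a four-patient group must be
  reported rather than erroring out of a cohort run.
* Two-sample comparisons: pooled-variance unpaired t-test by default
  (Welch by flag).
* Correlation: Pearson r with the Fisher-z 95% interval (coverage
  verified by simulation at n = 195) plus ordinary least-squares slope
  and intercept and the parameters needed to draw a confidence band.
* ROC: empirical AUC by the rank statistic (proved equal to trapezoidal
  integration of the empirical curve), DeLong variance for the 95%
  interval and for the test against AUC = 0.5 — the null we assume for
  the reported p-values, since the reporting format does not state one.
  The Youden cutoff maximizes `sensitivity + specificity − 1` over
  midpoints between observed values, with ties broken toward higher
  sensitivity and then the lower threshold; with `positive_is_low` (the
  default) a case is called positive when its score is at or below the
  cutoff, matching scores that fall with disease. Normal-vs-impaired ROC
  excludes the severe group (n = 4) as too small for a stable estimate.

## Numerical conventions and degenerate inputs

* Voxel indices are 0-based against the NIfTI affine; element
  `data[i,j,k]` is voxel `(i−1, j−1, k−1)`. All resampling targets the
  pre-contrast grid; world coordinates are in millimetres.
* Interpolation is trilinear with NA propagation (any stencil touching an
  invalid voxel is invalid) and an epsilon tolerance at the field-of-view
  edge so that exact-boundary samples are not spuriously dropped.
* Invalidity is represented as `NA` throughout; NIfTI export writes NaN
  for float types.
* Empty masks, single-class ROC labels, zero-variance correlations and
  sub-minimum group sizes raise typed validation errors (or typed
  "not assessable" results where a cohort report must survive them).
* All randomness is seed-derived via scoped RNG state, so identical
  (spec, seed) pairs are bit-identical and package calls never perturb
  the caller's RNG.

## Known limitations

* The built-in segmenter (Otsu + largest component + closing + hole
  fill) is phantom-only; clinical masks must be supplied externally, and
  they are used as given — whether vessels or lesions were excluded
  upstream is the mask producer's responsibility and directly shifts the
  volume-integrated score.
* The standard-grid normalization of the integrated convention is a
  reconstruction: it reproduces the published score scale for
  average-sized livers, but the original prototype's exact normalization
  is not recoverable from its description.
* The voxel-mean convention assumes the tabulated percentages are voxel
  means; a median-based aggregation would differ on skewed uptake
  distributions.
* Registration quality is validated on smooth synthetic fields; sliding
  interfaces (liver vs. body wall) and large local deformations are
  outside the validated regime.
* MELD is implemented in its UNOS variant; sites using other variants
  (e.g. MELD-Na) will see systematic group-boundary differences.
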