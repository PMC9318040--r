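# melif — automated liver-function scoring from Gd-EOB-DTPA-enhanced MRI

`melif` quantifies regional and whole-liver function from paired pre- and
post-contrast (hepatobiliary-phase) T1 relaxometry. Gadoxetic acid
(Gd-EOB-DTPA) is taken up by functioning hepatocytes and shortens T1, so
the voxel-wise T1 reduction rate is a proxy for regional liver function.
The package implements the full automated chain — T1 map fitting,
registration, masking, scoring, and cohort-level diagnostic statistics —
plus a digital liver phantom so every stage can be validated end-to-end
without clinical data.

**Who it is for:** imaging scientists evaluating MRI-based liver-function
biomarkers, and method developers who need a reproducible, fully synthetic
test bed for T1-relaxometry scoring pipelines.

## The model

Per voxel, with the post-contrast map registered onto the pre-contrast
grid:

    rrT1 = (T1_pre − T1_post_reg) / T1_pre × 100   (%)

Whole-liver aggregation comes in two conventions:

* `mean_pct` — the arithmetic voxel mean, the quantity reported as
  "rrT1_liver (%)";
* `integrated` — the fractional reduction summed over the liver on a
  fixed 3.6 mm isotropic standard grid: a dimensionless total that scales
  with functional liver volume.

The personalized score normalizes the integrated total by body size:

    f_p   = height^0.6 / (weight^0.3 × livervolume^0.6)     (m, kg, mL)
    MELIF = c × f_p × rrT1_integrated,   c = 0.694

The clinical reference is the lab-based MELD score
(`round(10(0.957 ln creat + 0.378 ln bili + 1.120 ln INR + 0.643))`,
UNOS clamping rules, floor 6), stratified as ≤ 10 normal / 11–18
impaired / > 18 severely impaired liver function.

## Worked example

```r
library(melif)

# a synthetic patient with impaired liver function, and their ground truth
pat  <- make_patient("impaired", seed = 11)
spec <- phantom_spec(seed = 11, deformation_amplitude_mm = 0)
gt   <- make_ground_truth(spec, pat)

res <- score_patient(gt$t1_pre, gt$t1_post, gt$mask, as.list(pat[1, ]))
res
#> Liver function score
#>   rrT1_liver (mean %):    45.23
#>   rrT1 (integrated):    18112.4
#>   f_p:                   0.003414
#>   MELIF:                  42.92
#>   MELD: 11 (impaired)
#>   voxels used/excluded: 29319/0
```

The phantom defines `T1_post = T1_pre × (1 − uptake)`, so the mean
reduction rate (45.2%) equals this patient's generated mean uptake
fraction (0.452) to within interpolation error, and the MELIF value of 43
sits in the impaired band of the 20–80 score scale — consistent with the
patient's MELD of 11.

Cohort-level validation (195 patients, 132/59/4 by severity, scored in
memory and summarized):

```r
spec   <- phantom_spec(seed = 500, deformation_amplitude_mm = 0,
                       grid_shape = c(72, 64, 56))
cohort <- score_phantom_cohort(c(normal = 132, impaired = 59, severe = 4), spec)
cohort_report(cohort)
#> MELIF group means 55.0 / 39.8 / 26.6, MELIF-vs-MELD r = -0.53,
#> ROC normal-vs-impaired AUC 0.807 (0.74 to 0.88)
```

## Command line

`exec/melif` exposes the pipeline as subcommands:

```sh
melif simulate --out cohort/ --normal 2 --impaired 1 --seed 7
melif t1fit    --angles 2,15 --tr 5 --out t1.nii.gz fa02.nii.gz fa15.nii.gz
melif mask     --image hbp.nii.gz --phantom-segment --out mask.nii.gz
melif register --fixed t1_pre.nii.gz --moving t1_post.nii.gz --out field.nii.gz
melif score    --t1pre t1_pre.nii.gz --t1post t1_post.nii.gz \
               --mask mask.nii.gz --patient-csv cohort.csv --out out/
melif run      --manifest cohort/manifest.json --out results/
```

## Documentation

The methods vignette (`vignettes/melif-methods.Rmd`) describes the model
and its assumptions, the phantom's stated world and its limits, the
registration algorithm, numerical conventions, and known limitations.
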