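# thoravol

Threshold-based quantification of intra-thoracic fat volume (ITFV) from
sagittal fat-bright MR stacks, with CT-anchored calibration of the
threshold, STRM myocardial scar quantification on late gadolinium
enhancement (LGE) stacks, and the downstream cohort statistics — built
for studying visceral adiposity as an imaging biomarker of myocardial
infarction risk in the metabolic syndrome. Because MR signal has no
absolute scale, a pixel inside the manually traced intra-thoracic border
counts as fat iff

    v >= mu + k * sigma

where mu and sigma are the pooled mean and SD of circular paravertebral
muscle reference ROIs and k = 10 for fat (k = 5 for the
signal-threshold-versus-reference-myocardium scar rule, with remote
myocardium as reference). Total ITFV is the per-slice fat area summed
over slices times the effective slice spacing (thickness + gap), in ml,
optionally indexed to body mass index. The multiplier can be calibrated
objectively against the conventional CT adipose window (−190 to −30 HU)
by maximizing Dice overlap on co-registered MR/CT pairs. The package
also ships synthetic thoracic MR/CT phantoms, LV LGE phantoms and
four-group cohort simulators with exact ground truth, so the entire
pipeline is testable without patient data.

Intended users: imaging scientists and biostatisticians building or
validating threshold-based adiposity / scar quantification pipelines.

## Worked example

```r
library(thoravol)

# a synthetic patient: paired MR/CT stacks, traced contours, muscle ROIs,
# and known fat truth
b <- make_thoracic_phantom(thoracic_phantom_spec(seed = 7))
b
#> <phantom_bundle> 8x128x128, truth volume 84.48 ml (3300 fat voxels), 8 contours, 40 ROIs

res <- quantify_itfv(b$mr, b$thoracic_contours, b$muscle_rois, k = 10, bmi = 30)
res
#> <itfv_result> threshold 149.2 (k = 10, ref 100.2 +/- 4.908), volume 84.48 ml, indexed 2.82 ml/kg/m^2 (BMI 30.0)
```

The reference ROIs estimate the muscle signal as 100.2 ± 4.9, giving a
10-SD threshold of 149.2; everything inside the contours at or above it
is fat, and slice summation recovers the generator's 84.48 ml exactly on
this phantom. STRM scar works the same way at k = 5 inside the
endo/epicardial annulus:

```r
lv <- make_lv_phantom(0.25, remote_sd = 2, seed = 7)
geom <- myocardial_geometry(lv$endo, lv$epi, lv$reference_region)
scar_percent(lv$lge, geom, k = 5)
#> [1] 25
```

Calibration against CT on a phantom pair built with partial-volume rims
(intermediate MR signal, non-fat on CT) peaks at the construction
multiplier:

```r
spec <- thoracic_phantom_spec(seed = 7,
  rois_per_slice = 6, roi_diameter_mm = 10,
  fat_signal_range = 100 + c(10.5, 11.5) * 5,
  rim_thickness_px = 2, rim_signal_range = 100 + c(4.5, 10.2) * 5)
b2 <- make_thoracic_phantom(spec)
calibrate_k(b2$mr, b2$ct, b2$thoracic_contours, b2$muscle_rois, k_grid = 8:12)
#> <calibration_result> selected k = 10 over 8 slices
#>   k mean_dice
#>   8    0.9758
#>   9    0.9858
#>  10    0.9970
#>  11    0.8280
#>  12    0.5000
```

The cohort layer simulates the four study cells and applies
distribution-aware comparisons, the collinearity-screened infarct
regression and Bland-Altman agreement:

```r
co <- simulate_cohort(cohort_spec(seed = 7))
compare_groups(co, "indexed_itfv")
#> <group_comparison> indexed_itfv by kruskal: statistic 9.878, p = 0.01964
#>   MetS-/MI-    n= 16  25.91 (9.61 - 51.10)
#>   MetS+/MI-    n= 32  34.60 (9.01 - 48.38)
#>   MetS-/MI+    n= 30  29.83 (2.20 - 58.56)
#>   MetS+/MI+    n= 32  37.33 (10.26 - 62.24)

bland_altman(c(10, 20, 30), c(12, 18, 33))
#> <agreement_result> bias -1, limits of agreement (-6.186, 4.186), r = 0.971, n = 3
```

(One seed's Kruskal-Wallis p of 0.0196 reflects a normality rejection in
one group; other seeds select ANOVA.) A thin command-line front end over
the same functions lives at `inst/cli/thoravol.R` with subcommands
`synth | itfv | calibrate | scar | compare | regress | agreement | run`,
reading NIfTI volumes, JSON contours/ROIs/geometry and CSV cohorts.

See `vignettes/thoravol-methods.Rmd` for the model, the synthetic-data
design and all numerical conventions.

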