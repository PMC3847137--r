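---
title: "Threshold-based intra-thoracic fat volumetry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold-based intra-thoracic fat volumetry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thoravol)
```

## The measurement problem

Visceral adipose tissue accumulates in the thorax of patients with the
metabolic syndrome and is a candidate imaging biomarker of ischemic risk.
On single-shot fast spin-echo (HASTE) MR images fat is bright relative to
every other tissue, so a total intra-thoracic fat volume (ITFV) can be
measured from an ordinary sagittal localizer stack without ionizing
radiation: trace the intra-thoracic border on each slice, normalize the
signal scale against a reference tissue, threshold, and sum areas across
slices. `thoravol` implements that measurement, the CT-anchored
calibration of its one free parameter, the analogous scar quantification
on late gadolinium enhancement (LGE) stacks, and the cohort statistics
used downstream — together with synthetic phantoms and cohorts carrying
exact ground truth, so every stage is testable without patient data.

## The segmentation model

MR signal has no absolute units, so the threshold is anchored to a
reference tissue. Given circular regions of interest traced on
paravertebral muscle, the reference statistics are the mean $\mu$ and
standard deviation $\sigma$ of the *pooled* ROI pixel population (SD with
the $n-1$ denominator). A pixel at value $v$ inside the traced
intra-thoracic border is classified fat iff

$$ v \;\ge\; \mu + k\,\sigma , $$

with the multiplier $k = 10$ for thoracic fat and $k = 5$ for the STRM
(signal threshold versus reference myocardium) scar rule, where the
reference region is remote myocardium inside the endo/epicardial annulus.
The comparison is inclusive, mirroring the "$\ge k$ SD" convention.

Pooling all ROI pixels into one population, rather than averaging per-ROI
means, was a deliberate choice: the clinical description of "the mean
signal and SD of these regions" is ambiguous, and pooling uses every
pixel, is deterministic, and makes the SD estimate tighter at no cost.

Volume is a slice summation: fat pixel count per slice times the in-plane
pixel area, times the through-plane extent each slice represents, summed
over slices, divided by 1000 to give ml. For a gapped 2-D acquisition
(8 mm slices, 2 mm gap in the thoracic protocol) the default
through-plane extent is the *effective slice spacing*, thickness + gap =
10 mm, treating each slice as representative of its full slab; the
alternative reading (thickness only) systematically undercounts by
gap/(thickness+gap) = 20% and is available via
`itfv(..., integration = "thickness")`. Indexed ITFV is volume divided by
body mass index (ml per kg/m²). Scar burden is reported as a voxel-count
percentage of the myocardial annulus — tissue density cancels, so no
absolute mass is needed.

## Geometry and rasterization

Volumes are `(slice, row, col)` arrays with pixel centers at integer
coordinates; contours are closed simple polygons in pixel units and ROIs
physical discs. A pixel belongs to a contour region iff its center lies
inside the polygon under the even-odd rule; centers exactly on an edge
are resolved deterministically by a fixed $+10^{-9}$ row offset, which
makes rasterization independent of vertex orientation. ROI membership is
a physical distance test against the in-plane spacing. The JSON
interchange files store 0-based coordinates; the R API is 1-based.

Degenerate inputs worth knowing about: a *zero* reference SD makes the
threshold collapse to the reference mean, and the inclusive comparison
then captures every reference-valued voxel. For thoracic volumetry this
is harmless because the muscle reference lies outside the traced border
and intra-thoracic non-fat tissue is far darker; for the LGE annulus the
reference lies inside the analysed region, so `scar_percent()` warns when
it happens. Noise-free behaviour of the scar pipeline is therefore
exercised at negligible noise (reference SD small against the 5-SD
separation, misclassification probability below $3\times10^{-7}$) rather
than at literal zero.

## Calibrating the multiplier against CT

On CT, adipose tissue occupies a calibrated Hounsfield window, −190 to
−30 HU, so a co-registered CT stack provides an anchor for choosing $k$.
`calibrate_k()` replaces the original visual matching with an objective
criterion: for each $k$ in a grid (default integers 4–16) it segments the
MR at $\mu + k\sigma$, segments the CT by the HU window, and scores the
per-slice Dice overlap averaged over analysed slices; the selected $k$
maximizes mean Dice, with ties resolved toward the smaller (more
inclusive, hence conservative for fat volume) multiplier. Registration is
assumed done — the phantom pairs are constructed congruent, as the
clinical workflow's anatomically matched multiplanar reformats were.

## What the synthetic data emulate — and what they do not

**Thoracic phantoms** have three compartments: low-signal
interior/background tissue, a posterior paravertebral muscle band lying
*outside* the traced border (where the reference ROIs are placed,
guaranteed disjoint from fat), and ellipsoidal fat deposits inside the
border. MR compartments are Gaussian (clipped at zero), CT compartments
uniform within their HU ranges, air constant at −1000 HU. Gaussian rather
than Rician noise is intentional: the method consumes only means and SDs
of tissue classes, and Gaussian compartments keep every tail prediction
analytic, so tests can assert, e.g., that the missed-fat fraction at a
threshold $t$ equals $\Phi((t-\mu_f)/\sigma_f)$ within binomial error.

For calibration experiments the generator offers two extra constructs: a
uniform fat signal band placed just above $\mu + 10.5\sigma$, and a
partial-volume rim shell around each deposit with intermediate MR signal
(up to $\mu + 10.2\sigma$) that is non-fat on CT — emulating the mixed
voxels at fat boundaries. By construction every $k < 10$ then admits rim
false positives and every $k > 10$ loses fat, so the Dice curve peaks at
the multiplier the phantom was built around; reference sampling is
generous (six 10 mm ROIs per slice) so the estimated threshold is tight
against the band edges.

**LV phantoms** build an annular myocardium between concentric polygonal
endo/epicardial contours and mark a contiguous angular sector containing
the requested fraction of annulus voxels as scar (count-matched per
slice, so the target fraction is honoured to rounding error), with the
reference ROI mid-wall in the middle of the remote arc.

**Cohorts** draw four study cells — MetS−/MI−, MetS+/MI−, MetS−/MI+,
MetS+/MI+ — with sizes 16/32/30/32 and indexed-ITFV means/SDs 22.3±10.6,
28.6±12.6, 30.6±12.3 and 35.2±11.4 ml/kg/m², plus BMI, age, sex, race,
diabetes, GFR, waist and hypertension at group-typical values. Scar % in
the MI+ cells follows a linear coupling,
$\text{scar} = a_g + 0.8 \times \text{indexed ITFV} + \varepsilon$,
$\varepsilon \sim N(0, 11)$, with per-group intercepts derived from the
target scar means (21.1 and 21.0 % LV mass) — a single linear law cannot
reproduce both group means given their different ITFV means, so the
per-group intercept is the default and a scalar `scar_intercept` override
exists. All non-negative quantities are truncated at zero by
*resampling*, not clipping, which preserves approximate normality near
the bulk. Waist circumference is generated with correlation 0.8 to
indexed ITFV so the regression's collinearity screen has a realistic
trigger.

Two consequences of the truncation deserve emphasis. First, large-sample
group means converge to the lower-truncated normal mean
$\mu + \sigma\,\phi(\mu/\sigma)/\Phi(\mu/\sigma)$, not to $\mu$; tests
use that closed form as their oracle. Second, where truncation is active
the realized scar–ITFV relation is no longer the nominal linear law, and
an OLS slope fitted to such data is attenuated below the generating
coefficient — not an estimator defect but a property of the truncated
generative process. Slope-recovery experiments therefore use a positive
common intercept (e.g. 30) at which truncation is inactive and the linear
law actually generates the data.

The phantoms do not model coil shading, bias fields, respiratory motion,
partial volume beyond the explicit rim construct, Rician magnitude noise,
or anatomy; the cohorts do not model measurement error in ITFV itself or
missingness. Green tests therefore demonstrate correctness of the
*computations* under known truth, not clinical performance on real scans.

## Statistical layer

`compare_groups()` mirrors standard practice: per-group Shapiro-Wilk
normality checks at α = 0.05 (the criterion is configurable; the clinical
description names none), then Welch's t test or one-way ANOVA when all
groups pass, Mann-Whitney U or Kruskal-Wallis otherwise, all two-tailed,
with summaries in the matching idiom (mean ± SD vs median/range). The
Welch variant is the default t test because equal variances are not
assumed; `var_equal = TRUE` restores the pooled test. Categorical tables
use Fisher's exact test for any 2×2 with an expected cell below 5 and the
chi-square test otherwise. The infarct regression is OLS with a
sequential pairwise collinearity screen: candidates (in the order given)
whose |r| with an already-included predictor exceeds 0.7 (configurable)
are excluded and reported with the offending pair — binary predictors
enter the screen as 0/1 point-biserial correlations. Bland-Altman
agreement reports bias = mean(A−B), the SD of differences, and limits of
agreement bias ± 1.96 SD; reported reproducibility intervals of this
width are limits of agreement, not confidence intervals of the bias, and
that is what the package computes.

The reproducibility harness emulates repeated manual analysis by
re-measuring phantoms under Gaussian jitter of contour vertices and ROI
centers — small jitter twice for the intra-rater comparison, larger
jitter for the inter-rater one — and summarizes each comparison with
Bland-Altman statistics and Pearson's r.

## Problem sizes and numerical tolerances

The test-suite and acceptance experiments run at deliberately compact
sizes chosen to keep every Monte-Carlo assertion well-powered: thoracic
phantoms of 6–8 slices at 96²–128² pixels (1.6 mm in-plane, 8+2 mm
slices), a fine-grid phantom of 24×128² at 2 mm slices for tail checks
(≥10⁴ fat voxels), LV phantoms of 4 slices at 192², 30 seeded calibration
replicates over k = 4…16, 2000 null replicates for the type-I check, 500
for power, and 200 for slope recovery. Rasterization agreement is checked
against an exhaustive point-in-polygon oracle; volumetry against a
brute-force per-voxel loop, bit-for-bit.

## Known limitations

Automatic tracing of the intra-thoracic border, fat/water separation
(Dixon) methods, MR–CT registration, DICOM series handling and
transmurality scoring are out of scope. The ±1.96 limits assume
approximately normal differences; the collinearity screen is pairwise,
not a variance-inflation analysis; and the multiplier calibration
inherits the resolution of its k grid.
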