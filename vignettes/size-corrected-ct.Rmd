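---
title: "Size-corrected quantitative CT assessment of renal fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-corrected quantitative CT assessment of renal fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalqct)
```

## The problem

Fibrotic renal cortex contains collagen, and collagen is denser than normal
parenchyma: tendons (mostly collagen and water) measure roughly 75–115 HU on
non-contrast CT against 20–40 HU for healthy kidney. Modelling fibrotic
cortex as a volume mixture, a kidney with fibrosis volume fraction $f$ has
mean CT number $(1-f)\,k + f\,c$ with $k, c$ the midpoints of those ranges,
a relative increase of $100\,f\,(c-k)/k$ percent — about 10.8% at $f = 0.05$
(`predicted_ct_increase(0.05)`). Since quantitative CT coefficients of
variation are a few percent, even minimal fibrosis should be detectable,
*if* one confound is removed: beam hardening. A polychromatic x-ray beam
loses its soft photons preferentially as subject size grows, so measured
CT numbers drift downward with size, by enough to swamp the fibrosis signal
across a cohort of differently sized subjects.

## The size index and the calibration model

The package computes the subject-size surrogate directly from the scan. For
an axial slice, the **total signal index** is

$$\mathrm{TSI} = \frac{(\overline{\mathrm{HU}}_{\mathrm{FOV}} -
\mathrm{HU}_{\mathrm{air}}) \times \mathrm{area}_{\mathrm{FOV}}}{10^7},$$

with $\mathrm{HU}_{\mathrm{air}} = -1024$ by default (configurable; some
scanners use $-1000$). Subtracting air makes the index non-negative, and the
$10^7$ divisor scales a small-primate cohort into roughly $(0, 10)$. The FOV
region is the reconstruction circle centred in the matrix; voxels outside it
contribute to neither the mean nor the area. The competing index is the
tissue **cross-sectional area** (CSA, mm²); because CSA is traditionally
hand-traced, `compute_csa()` offers a reproducible automatic stand-in
(threshold $> -400$ HU, disc closing of radius 2 voxels, hole filling) and
always defers to a supplied ROI. Animal-level indices average three axial
slices intersecting the cortical ROIs.

Against a QCT phantom (four regions at 0, 50, 100, 200 mg/ml calcium
hydroxyapatite scanned along with subjects of varying size), each region's
ROI mean follows

$$\mathrm{CT\#} = B - A \ln(\text{size index}),$$

so $B$ is the CT number at size index 1 and $A$ the HU lost per $e$-fold of
size. `ct_calibration()` fits each region by OLS on $\ln(\text{size})$,
compares TSI and CSA by Gaussian ML AIC of the full four-region interaction
model, tests slope homogeneity of the soft-tissue-bracketing regions P1–P2
with a Wald test of the region × ln(size) interaction
($(\hat\beta/\mathrm{SE})^2 \sim \chi^2_1$, $\alpha = 0.05$, the
conventional reference distribution and level for a Wald test of
interaction), and fits the common-slope model whose pooled $A$
drives the correction. Cortical tissue falls between the P1 and P2
densities, which is why those two regions are pooled.

```{r calibration}
obs <- simulate_phantom_observations(seed = 1)
cal <- ct_calibration(obs)
summary(cal)
```

## The correction

With the pooled coefficient and a cohort reference size,

$$\mathrm{corrected}_i = \mathrm{measured}_i +
A \ln\!\left(\frac{\mathrm{size}_i}{\overline{\mathrm{size}}}\right).$$

The reference defaults to the loaded cohort's mean animal size index
(recomputed per analysis set, so every cohort is normalized to its own
average size); a fixed reference can be supplied for cross-study
comparability. An exactly average-sized animal is untouched; two kidneys
with identical true tissue measured at different sizes correct to identical
values when the generating bias follows the calibration model — an algebraic
cancellation the test suite verifies numerically.

## Histological ground truth

Masson trichrome renders collagen blue. `blue_area_fraction()` counts pixels
inside HSB windows (ImageJ's 0–255 scale) and divides by ROI area; section
values average 3 ROIs × 2 masked reads. The default blue window (hue
140–200, saturation ≥ 60, brightness ≥ 40) separates the generator's blue
class from pink tissue and white space; the original ImageJ thresholds are
unpublished, so the defaults are explicitly configurable and should be tuned
on reference swatches per stain batch. Semiquantitative 0–4 reader scores
are averaged over two reads, and fibrosis — the positive class throughout
the diagnostics — is a mean score of at least 1.

## Diagnostics

`evaluate_fibrosis_ct()` reproduces the evaluation battery: GEE logistic
regression of fibrosis on corrected HU with exchangeable working correlation
over the two kidneys per animal and sandwich SEs (no GEE fitting package is
declared; the Fisher-scoring estimator is implemented here and collapses to
ordinary logistic ML for singleton clusters, which the tests exploit as an
oracle); empirical ROC with cutoffs at midpoints between distinct scores
plus infinite endpoints, ties called negative, AUC by trapezoid (equal to
Mann–Whitney concordance), PPV/NPV at observed prevalence; paired
right-minus-left t-tests; Welch group comparisons after animal-level
aggregation; and method correlations from a mixed model with random
intercepts for animal and kidney (method as fixed effect, both methods
standardized), reported as the shared-variance fraction
$(\sigma^2_a + \sigma^2_k)/(\sigma^2_a + \sigma^2_k + \sigma^2_e)$ with the
plain Pearson estimate always alongside — the exact variance structure
behind the published correlation is unstated, so both are exposed rather
than guessed. The estimator reduces to Pearson when each animal contributes
one kidney.

```{r study, warning = FALSE}
cohort <- simulate_cohort(seed = 2)
report <- evaluate_fibrosis_ct(cohort, cal)
report
```

## What the generators emulate — and what they do not

The synthetic module is first-class: every pipeline stage can be validated
against known truth.

* `simulate_phantom_observations()` draws sizes log-uniformly over TSI
  (2, 9) and CT numbers from the calibration line plus Gaussian noise
  (default SD 1 HU, a realistic phantom-ROI repeatability). Default slopes
  (30, 30.5, 45, 60) grow with density, with P1/P2 nearly identical so the
  pooling decision mirrors the studied scanner; CSA is proportional to TSI
  with log-normal decoupling noise so the AIC comparison has a true winner.
* `simulate_cohort()` emulates the study design (10 total-body, 10
  chest-only, 2 control animals; two kidneys each): per-group latent
  fibrosis scores (means 2.0 / 0.5 / 0.1, rounded to the half-point scale),
  true HU $= 46 + 5.5 \times \mathrm{score}$ spanning the observed
  45–65 HU corrected range, animal-level biological HU variation (SD 3) and
  2 HU measurement noise, with the beam-hardening bias injected at
  measurement level as $-A\ln(\mathrm{size}/\mathrm{size}_0)$, $A = 30$.
  That magnitude makes uncorrected CT numbers nearly uninformative across a
  size-varied cohort — the situation the correction exists for. The bias is
  injected through the same equation the calibration fits, a deliberate
  choice that makes truth exactly recoverable; it does not simulate spectral
  physics, reconstruction artifacts or anatomy, so passing tests certify
  the statistical machinery, not scanner-specific behaviour.
* `render_ct_slice()` builds ellipse phantasms with matching ROI masks so
  raster TSI can be checked against the analytic area-weighted value;
  `render_trichrome()` renders blue/pink/white classes with per-pixel jitter
  and then adjusts class assignment pixel-by-pixel so the realized blue
  fraction hits the target exactly (within $1/n_{\text{pixels}}$).

## Numerical choices and edge cases

* Rasterization: a voxel belongs to a polygon ROI iff its centre is inside
  under the even-odd rule; voxel indices are 0-based and physical
  coordinates are mm at voxel centres. One stated convention, hand-countable.
* AIC uses `stats::AIC`'s Gaussian profile-likelihood form
  ($n\ln(\mathrm{RSS}/n) + 2k$ plus an additive constant); the constant
  cancels in every comparison made.
* The GEE working correlation is moment-estimated and bounded to
  $[-1/(n_i-1) + 0.05,\ 0.95]$: at the $\pm 1$ boundaries the exchangeable
  inverse degenerates and highly concordant kidney pairs can otherwise push
  the estimate into it. Perfect separation is detected (all fitted
  probabilities degenerate and perfectly classifying) and flagged rather
  than masked.
* Degenerate inputs error early and name the offender: empty ROIs, mixed
  DICOM series, missing rescale metadata, rank-deficient calibration
  designs, single-class outcomes, out-of-range scores.
* Unknown-side kidneys are resolved by choosing one scan at random under a
  recorded seed, and the diagnostics expose an exclusion flag for the
  matching sensitivity analysis.

## Problem sizes used in validation

The shipped tests and the acceptance script use 150–500 replicate
simulations for coverage/recovery checks, cohorts of 22–100 animals,
100–120 px histology tiles and 256–512 px slice rasters — sizes at which
the Monte-Carlo bands quoted in the tests are comfortably stable.

## Known limitations

DICOM support covers explicit-VR little-endian CT series (the subset the
package itself writes); anything more exotic should arrive as NIfTI. Cortex
and histology ROIs are ingested, never derived — segmentation, cyst
exclusion and artery avoidance are the ROI author's responsibility. The
calibration is scanner-specific by design: coefficients fitted on one
scanner do not transfer, and the package always derives $A$ from data
rather than shipping a constant.
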