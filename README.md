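# renalqct

Detection and quantification of renal cortical fibrosis from **non-contrast
CT**, for imaging scientists and preclinical researchers working with
HU-calibrated scans (e.g. irradiated non-human primate cohorts developing
radiation nephropathy).

Fibrotic cortex contains collagen (75–115 HU) in place of normal parenchyma
(20–40 HU), so even 5% fibrosis by volume should raise the mean cortical CT
number by ~10% — well above typical quantitative-CT repeatability. The
catch is beam hardening: measured CT numbers fall as subject size grows, by
enough to bury the fibrosis signal across a cohort of differently sized
subjects. `renalqct` implements the full correction workflow:

1. **Size index from the scan itself.** The total signal index
   `TSI = (mean FOV HU − air HU) × FOV area / 1e7` (and the competing
   cross-sectional area, CSA), averaged over three axial slices per animal.
2. **Phantom calibration.** QCT phantom regions (0/50/100/200 mg/ml calcium
   hydroxyapatite) scanned across subject sizes obey
   `CT# = B − A·ln(size index)`; `ct_calibration()` fits each region,
   compares TSI vs CSA by AIC, Wald-tests slope homogeneity of the
   soft-tissue-bracketing regions P1–P2, and pools their slope.
3. **Correction.**
   `corrected = measured + A·ln(size_i / mean size)` — a closed-form
   normalization of every kidney to the cohort's average subject size.
4. **Histology ground truth.** Blue-area fraction of Masson-trichrome
   sections by HSB colour thresholding (3 ROIs × 2 masked reads), plus
   semiquantitative 0–4 scores binarized at mean ≥ 1.
5. **Diagnostics.** GEE logistic regression (exchangeable correlation over
   kidney sides within animal, sandwich SEs), empirical ROC/AUC with
   operating points, paired left/right tests, group comparisons, and
   mixed-model method correlations.

A synthetic-data module (`simulate_phantom_observations()`,
`simulate_cohort()`, `render_ct_slice()`, `render_trichrome()`) generates
every input with known ground truth, so the whole pipeline is testable
without scanner access. I/O covers NIfTI and explicit-VR little-endian DICOM
series, polygon/mask ROI sets (JSON), cohort tables (CSV) and PNG/TIFF
histology.

## Worked example

```r
library(renalqct)

# the area-weighted mixture prediction motivating the method
predicted_ct_increase(0.05)
#> [1] 10.83333

# calibrate the scanner's size artifact on (simulated) phantom observations
obs <- simulate_phantom_observations(seed = 1)
cal <- ct_calibration(obs)
cal
#> Phantom beam-hardening calibration: CT# = B - A ln(size index)
#>   size index: TSI; 72 observations in 4 regions
#>   pooled A (P1+P2): 30.499 (SE 0.354)

# correct a cohort and run the diagnostic battery
cohort <- simulate_cohort(seed = 2)
report <- evaluate_fibrosis_ct(cohort, cal)
report
#> Fibrosis CT diagnostic report
#>   kidneys: 44; fibrosis prevalence: 55%
#>   AUC (corrected HU vs fibrosis): 0.963
#>   group means (total_body vs chest_only): 59.7 vs 51.1 HU, p = 0.00689
#>   r(score, corrected HU) = 0.92

operating_point(report$roc, 51)
#>   cutoff sensitivity specificity       ppv    npv
#> 1     51   0.9583333        0.75 0.8214286 0.9375
```

The pooled `A` is the HU lost per *e*-fold of subject size; the report's
AUC quantifies how well size-corrected cortical HU separates fibrotic
(mean score ≥ 1) from non-fibrotic kidneys; the 51 HU row is an example
decision threshold with its confusion-matrix metrics at the cohort's
observed prevalence.

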