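# tmemorph

Morphometry of the tumor microenvironment (TME) on histopathology
tissue-segmentation images, for predicting pathological complete
response (pCR) to neoadjuvant chemotherapy in HER2-positive breast
cancer.

The package is aimed at computational-pathology researchers who work
with tile-resolution tissue label maps rather than raw pixels. It
covers the full analysis chain:

* **Tiling** of RGB slides into 175 px tiles with per-slide Otsu tissue
  detection and a 20% minimum-tissue filter.
* **Tissue-segmentation images (TS-images)**: one compartment code per
  tile — excluded (0), tumor (1), stroma (2), necrosis (3),
  intratumoral lymphocytes / iTIL (4), stromal lymphocytes / sTIL (5) —
  built by a sequential binary classification cascade (tumor→necrosis→
  lymphocyte) over any pluggable tile classifier, or read directly from
  PNG label grids.
* **Connected-component morphometry**: 8-connected components per
  compartment, 11 shape descriptors per component (area, filled area,
  convex area, axis lengths, eccentricity, Euler number, extent,
  solidity, perimeter, orientation), aggregated into **46 features per
  compartment** under three strategies — all regions (12), largest
  region (11), and *significant* regions, those strictly exceeding 5%
  of the largest component's area (23).
* **Baseline metrics**: per-compartment tile counts and the relative
  ratios TSR, iTR, sTR, TISR and lymphocyte density.
* **Prediction**: fusion with clinical covariates (ER/PR status and
  percentage, HER2/CEP17 ratio), training-only standardization,
  stratified 10-fold cross-validated LASSO selection maximizing AUC,
  and an L2-regularized single-hidden-layer MLP; evaluation by AUC, F1,
  PPV, recall and NPV, plus learning curves over training fractions and
  sweeps of the significant-region threshold.
* **Univariate statistics**: Mann-Whitney U, Chi-square / Fisher exact,
  and Spearman correlation against residual infiltration size (RIS,
  zero by definition for pCR patients).
* A **seeded synthetic cohort generator** that plants configurable
  group differences on sTIL component count and area, plus clinical
  covariates and RIS, so every stage is testable against known ground
  truth.

## Worked example

```r
library(tmemorph)

# a synthetic two-arm cohort with a planted sTIL effect
train <- generate_cohort(cohort_config(n_patients = 140,
                                       pcr_fraction = 0.5,
                                       effect_size = 1.5, seed = 7))
eval  <- generate_cohort(cohort_config(n_patients = 60,
                                       pcr_fraction = 0.5,
                                       effect_size = 1.5, seed = 1007))

train[[1]]$ts
#> ts_image 'P001': 48 x 48 tiles
#>    n_tumor   n_stroma n_necrosis     n_itil     n_stil n_excluded
#>        816       1143         20         18        122        185

# patients x features tables (46 sTIL morphology features + clinical)
tr <- cohort_feature_table(train, compartments = "stil")
ev <- cohort_feature_table(eval,  compartments = "stil")

fit <- run_pipeline(tr, ev, compartment = "stil", seed = 7)
fit
#> model_report: 140 train / 60 eval, 8 selected features
#>   AUC 0.907  F1 0.786  PPV 0.846  recall 0.733  NPV 0.765

importance_report(fit$weights)$favorable
#> [1] "stil__ar__n_components"      "stil__ar__filled_area__mean"
#> [3] "pr"
```

The held-out AUC of 0.907 says the model separates pCR from non-pCR
patients on unseen data; the favorable-weight list recovers the planted
signal — the number of sTIL components and their (filled) area — with
PR positivity contributing the planted clinical effect. On a null
cohort (`effect_size = 0, clinical_effect = 0`) the same pipeline
evaluates to chance-level AUC.

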