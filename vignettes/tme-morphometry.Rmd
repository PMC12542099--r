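---
title: "Tumor-microenvironment morphometry for pCR prediction: models and methods"
author: "tmemorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-microenvironment morphometry for pCR prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmemorph)
```

## The problem

Roughly a third of HER2-positive breast cancer patients fail to achieve a
pathological complete response (pCR) to neoadjuvant chemotherapy, and
routine clinical markers predict the outcome poorly. The spatial
organization of the tumor microenvironment (TME) on pre-treatment H&E
biopsy slides — in particular the amount and arrangement of stromal
tumor-infiltrating lymphocytes (sTILs) — carries predictive signal.
`tmemorph` implements a full morphometry pipeline that turns a slide into
a small set of interpretable shape features and a pCR prediction:

1. **Tiling** — the slide is cut into fixed-size tiles (175 px at 20x for
   real slides) and tiles with under 20% tissue by a per-slide Otsu
   threshold are excluded.
2. **Tissue segmentation** — a sequential binary classification cascade
   assigns each retained tile one compartment code: tumor vs stroma
   first, then necrosis within tumor (necrosis is terminal because it
   mimics intratumoral lymphocytes), then lymphocyte tests within tumor
   (iTIL) and stroma (sTIL). The result is a tile-resolution
   tissue-segmentation image (TS-image).
3. **Morphometry** — per compartment, 8-connected components are
   labelled and 11 shape descriptors computed per component; three
   aggregation strategies yield 46 features per compartment.
4. **Fusion and prediction** — morphological features are fused with
   five clinical covariates (ER/PR status and percentage, HER2/CEP17
   ratio), standardized on training rows, filtered by cross-validated
   LASSO, and fed to an L2-regularized multilayer perceptron.
5. **Statistics** — univariate Mann-Whitney / Chi-square / Fisher
   comparisons between outcome groups, and Spearman correlations with
   residual infiltration size (RIS; 0 by definition for pCR patients).

Because the clinical whole-slide cohorts this kind of analysis is built
on are access-restricted, the package ships a first-class synthetic
cohort generator with planted, configurable group differences, so every
stage is testable against known ground truth.

## Morphological feature model

Analysis happens at tile resolution: each tile is the unit of analysis
and areas are measured in tiles. For every compartment mask (tumor,
stroma, iTIL, sTIL, and the TIL union), maximal 8-connected components
are extracted and described by 11 descriptors: area, filled area, convex
area, major/minor axis length, eccentricity, Euler number, extent,
solidity, perimeter, and orientation.

Numerical conventions worth knowing:

* **Moments.** Axis lengths derive from second central moments with each
  tile treated as a unit square (adding 1/12 to the diagonal of the
  covariance). This keeps one-tile-wide bars from degenerating to a zero
  minor axis: a 1x5 bar has a 5:1 moment ellipse and eccentricity
  `sqrt(1 - 1/25)` rather than exactly 1.
* **Holes.** With 8-connected foreground, holes are 4-connected
  background regions that do not reach the bounding-box border; the
  Euler number of a single component is 1 minus the hole count.
* **Convex area** counts tiles whose centres fall inside (or on) the
  convex hull of the component's tile centres; collinear components
  degenerate to their own area.
* **Perimeter** counts exposed 4-neighbour tile edges — simple, exact,
  and additive under resolution doubling.

The three aggregation strategies produce the fixed 46-feature split per
compartment:

| strategy | features | content |
|---|---|---|
| all-region (AR) | 12 | component count + mean of each descriptor |
| largest-region (LR) | 11 | descriptors of the single largest component |
| significant-region (SR) | 23 | significant count + mean and SD of each descriptor |

A component is *significant* when its area **strictly exceeds** 5% (by
default) of the largest component's area; the boundary case at exactly
the threshold is dropped, and the largest component is always retained.
The SR standard deviation is the population form, so a lone significant
component reports SD 0 rather than a missing value. As the threshold
approaches zero the SR means converge to the AR means, which the tests
assert. An absent compartment yields `NA` sentinels which are imputed
downstream with training-set medians.

The descriptor list itself is configuration-level: the three strategy
blocks are assembled from `descriptor_names()`, so a revised descriptor
set slots in without touching the aggregation logic. The set shipped
covers every descriptor the analysis names directly (component count,
filled/convex area, axis lengths, eccentricity, Euler number) plus four
standard regionprops-style descriptors (extent, solidity, perimeter,
orientation) to reach the published cardinalities; AR aggregates by the
mean, the natural location summary when component counts vary per slide.

## The classification cascade

The cascade consumes any tile classifier conforming to the
`predict(tile) -> probability` contract, with a 0.5 cutoff per step by
default. Training convolutional classifiers is out of scope here — the
contribution exercised by this package is the downstream morphometry —
so the package ships a rule-based reference classifier pair with the
synthetic renderer: `render_slide()` encodes each tile's compartment in
its mean color (green channel separates tumor from stroma, red-minus-blue
marks necrosis, blue-minus-red marks lymphocytes) and
`reference_classifiers()` inverts the encoding. Color margins are about
50 standard deviations of a tile-mean under the default pixel noise, so
cascade reconstruction of the generator's ground truth is exact in
practice, and the test suite requires exact grid equality on 20 seeded
slides. Real TS-images can also be ingested directly (`read_ts_image()`),
bypassing classification entirely.

Within tumor tiles necrosis is tested before lymphocytes and is
terminal; the ordering is an explicit design choice motivated by the
morphological similarity of necrosis and iTILs.

## The synthetic cohort generator

`generate_cohort()` emulates a two-arm neoadjuvant cohort. Defaults are
fixed at study-like conditions: 85 patients with a pCR fraction of
36/85, 48 x 48 tile grids, non-pCR median RIS 1.35 cm, planted effect
size 1.5.

Layout: two independent smoothed-noise blob processes define excluded
regions (8% of the grid) and the tumor/stroma split (40% of tissue is
the tumor branch), so compartments have irregular, realistic shapes and
the marginal label fractions are near-deterministic. Necrosis (two ~10
tile blobs) and iTILs (about 3 components of ~6 tiles) are grown inside
tumor with no group difference. sTIL components are grown inside stroma
with mutual separation so the planted component count survives
labelling.

The planted signal acts on sTIL morphology, with `effect_size` the
*slide-level* standardized shift of each planted descriptor: component
count `round(N(8 + effect * 2, 2))`, and component areas drawn around a
slide-level location `N(8 + effect * 1.5, 1.5)` with within-slide spread
2 tiles. Splitting the area variance into between- and within-slide
parts keeps the per-slide mean-area feature at a standardized separation
close to `effect_size` instead of being amplified by within-slide
averaging. Clinical covariates: ER positive at rate 0.8; PR positivity
has base log-odds `logit(0.6)` shifted by `clinical_effect` for pCR
patients; percentages are uniform on [10, 100] given positivity and 0
otherwise; HER2/CEP17 is lognormal with median 3.1. Non-pCR RIS is
lognormal with configurable median, negatively coupled (rho 0.4) to the
planted sTIL burden; pCR patients have RIS exactly 0.

What the generator does *not* emulate: H&E texture, nucleus-level
structure, correlated morphology across compartments, scanner and stain
variation, and cohort shift between training and validation sites.
Passing tests therefore demonstrate the correctness and statistical
behavior of the pipeline machinery — not clinical performance on real
slides, which depends on trained tile classifiers and real cohorts.

```{r cohort-example}
co <- generate_cohort(cohort_config(n_patients = 4, seed = 1))
co[[1]]$ts
```

## Modeling choices

* **Standardization** centres and scales by training-row means and
  population SDs; zero-variance columns map to 0 and `NA` sentinels are
  imputed with training medians first. Nothing about the evaluation
  cohort enters any fit.
* **LASSO** is L1-penalized logistic regression over a glmnet path. The
  penalty is chosen by stratified 10-fold cross-validation maximizing
  mean held-out AUC — the same currency the models are judged in — with
  the AUC computed explicitly per fold (the stock cross-validation
  helper silently switches objectives for small folds). Ties resolve to
  the strongest penalty, keeping selections parsimonious.
* **MLP**: one hidden layer (`nnet`), hidden size over {4, 8, 16} and
  weight decay over {1e-3, 1e-2, 1e-1} tuned by the same stratified CV
  scheme, then refit on all training rows with a fixed seed. An empty
  LASSO selection degenerates to a constant 0.5 predictor rather than an
  error, so null cohorts evaluate to chance AUC cleanly.
* **Metrics**: AUC by rank concordance with half-credit ties (the
  Wilcoxon formulation); PPV, recall, NPV, F1 from the confusion matrix
  at a 0.5 cutoff; empty-denominator ratios are `NA`, not 0.
* **Folds**: when a minority class has fewer members than the requested
  folds, the fold count shrinks with a warning — relevant for small
  training fractions in learning curves.

Statistical conventions: all tests are two-sided; Mann-Whitney is exact
for two groups of at most 20 without ties and tie-corrected normal
otherwise; the categorical test is Fisher's exact unless every expected
cell count exceeds 5; Spearman uses midranks (the pCR block of zero RIS
values is heavily tied) with the t-approximation for its P value; raw P
values are reported at the 0.05 level with the number of tests annotated
rather than corrected.

## Problem sizes and reproducibility

Every stochastic step runs under an explicit seed: cohorts reproduce bit
for bit, fold assignments and MLP initialization derive per-component
seeds from one base seed, and the cohort writer emits byte-identical
files on repeated writes. The validation experiments use cohorts of
140 training / 60 evaluation patients on 48 x 48 grids (200 patients
and 51 features for selection-recovery runs, 20 replicate generations
for rate estimates, 10 subsampling replicates per learning-curve
fraction) — sizes chosen so planted effects are detectable at
conventional power while each experiment completes in seconds.

## Known limitations

* The 46-feature list reproduces the published cardinality but the
  original descriptor-by-descriptor naming is not public; the name list
  here is canonical for this package and stable across versions.
* The relative TME metrics (TSR, iTR, sTR, TISR, LD) use the natural
  denominators implied by their names; the originals are not published.
  They are isolated in `relative_metrics()` for easy revision.
* AR aggregation uses means; sum- or max-style aggregation would change
  feature scales but not the pipeline structure.
* The cascade assigns one hard label per tile at a 0.5 cutoff; mixed
  tiles are not modelled.
* Learning-curve and recovery rates are properties of the synthetic
  conditions stated above, not clinical performance estimates.
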