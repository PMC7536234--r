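---
title: "Ultrasound radiomics on synthetic phantoms: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ultrasound radiomics on synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usradiomics)
```

## Scope

`usradiomics` implements a 2D radiomics pipeline for greyscale ultrasound
regions of interest (ROIs): synthetic phantom generation, DICOM image/mask
input-output, a 232-feature catalog, univariate screening, and four
classification strategies with patient-level data hygiene. The motivating
application is radiogenomic screening — relating ovarian ultrasound texture
to a binary per-patient genotype (carrier vs wild-type of a germline
variant) — but every stage is generic in the binary outcome.

Because no clinical image archive ships with the package, the synthetic
phantom generator is a first-class module: it defines the study conditions
under which every downstream claim is tested.

## The phantom generator

Each phantom is an elliptical "ovary" on a darker background:

* **Geometry.** Semi-axes are drawn uniformly from 8–15 mm (a plausible
  adult ovary cross-section), with uniform rotation and a small centre
  jitter, rasterized at the machine's pixel spacing (0.30–0.40 mm/pixel by
  default) on a 128 x 128 grid. The ROI mask is the rendered ellipse minus
  any follicles.
* **Echogenicity.** Piecewise-constant: background grey 40, ovary 110 on
  the 8-bit scale. Zero to three dark circular follicles (30 % of the
  ovary grey, radius up to ~1.4 mm) are carved out of the mask as
  class-independent nuisance structure, mimicking functional cysts that a
  clinical protocol would not exclude.
* **Speckle.** Fully developed multiplicative speckle: a unit-mean Rayleigh
  field blended with weight `speckle_scale` (default 0.5) into the
  echogenicity map. The field is pixelwise independent; real B-mode speckle
  is spatially correlated by the point-spread function, so absolute texture
  values here should not be read as clinically realistic — only contrasts
  between classes are meaningful.
* **Class effect.** Bright spots (diameter 1–3 px, +60 grey) are planted at
  a Poisson rate of 1 per 100 ROI pixels; carriers receive rate and
  amplitude inflated by `1 + effect_size`. The label enters the generative
  law *only* through the spot parameters, so `effect_size = 0` makes the
  two classes exactly exchangeable — the null of the screening stage is
  true by construction, not approximately. The planted signature (more
  small clusters of high grey level) is deliberately the kind of texture a
  short-run/high-grey-level-emphasis feature detects, so recovery
  experiments have a known ground truth.
* **Machines.** Four scanner profiles differ by a monotone intensity map
  `clip(gain * 255 * (g/255)^gamma + floor)` and by pixel spacing. Each
  *patient* is assigned one machine; 1–4 images per patient are drawn as
  distinct side/plane views. Carrier prevalence defaults to 1/3.

Choices the generator does **not** model: beamforming, depth-dependent
attenuation and focus, correlated speckle, 3D anatomy, acquisition
operator variability. Passing tests therefore demonstrate the pipeline's
internal correctness and its ability to recover a planted texture effect —
not clinical performance.

## Feature catalog (232 features)

All features are computed on ROI pixels min–max rescaled to 0–255
("normalized"); this makes the texture pipeline invariant to any strictly
increasing affine transform of raw intensities (tested end to end). The
composition is:

| family | count | content |
|---|---|---|
| first order | 20 | histogram statistics of the normalized ROI values |
| morphology | 14 | area, perimeter, moment-ellipse axes, eccentricity, elongation, circularity, compactness, convex hull area, solidity, extent, maximum Feret diameter, equivalent disc diameter, centre-of-mass shift |
| texture | 183 | 25 co-occurrence (GLCM) features x 4 variants (directional-average and merged matrices at distances 1 and 2) = 100; 16 run-length (GLRLM) features x 4 directions = 64; 16 size-zone (GLSZM) features; 3 distance-zone (GLDZM) summaries |
| fractal | 15 | box-counting dimension after binarizing at thresholds 0.05, 0.10, ..., 0.75 of the normalized range |

Feature definitions follow the Image Biomarker Standardisation Initiative
where a standard exists. Published catalogs of this size rarely print every
member, so this composition is a reconstruction that reproduces the family
totals; the registry (`feature_catalog()`) is a single ordered table, so an
alternative composition can be substituted without touching the extractors.

Numerical conventions worth knowing:

* **Discretization.** `Ng = 32` uniform bins over `[0, 256)`,
  `level = min(Ng, floor(v' * Ng / 256) + 1)`. The bin count is the common
  radiomics default; matrices stay dense for ROIs of a few thousand pixels.
* **Degenerate textures.** A constant ROI normalizes to all zeros and gets
  fixed fallbacks (entropies 0, energies 1, correlation-type features 0)
  rather than missing values, so downstream tables stay rectangular.
* **Run/zone conventions.** Runs break at the mask boundary; zones are
  4-connected; the zone distance is the city-block distance to the ROI
  border with border pixels at distance 1.
* **Fractal fit.** Dyadic box sizes anchored at the mask bounding-box
  origin, unweighted least squares of `log N(s)` on `log s`; an empty
  thresholded set yields 0, and a single usable scale is flagged.
* **Morphology.** Moment-ellipse axes use the `4 * sqrt(eigenvalue)`
  convention with the 1/12 pixel-integration correction (a rasterized disc
  of radius R recovers axes 2R); the convex hull is taken over pixel
  corners so solidity cannot exceed 1; perimeter is the chain-code contour
  length, so perimeter-derived features (circularity, compactness) carry
  raster bias on small ROIs.
* **First-order on normalized values.** Whether first-order statistics are
  computed before or after rescaling is often left unstated in published
  pipelines; here *all* families use normalized values, as a documented
  convention (the centre-of-mass shift is the one feature that sees raw
  intensities).

One phantom extraction takes well under a second on one CPU; suite-level
experiments use cohorts of tens of patients to stay fast while keeping
group sizes statistically meaningful.

## Screening

Redundancy pruning removes zero-variance columns, then iteratively finds
the pair with the largest |Pearson r| above the threshold (default 0.9) and
drops the member with the larger mean absolute correlation — the classic
behaviour of R's `caret::findCorrelation(exact = TRUE)`, against which the
implementation is cross-checked. Ties drop the later catalog name, making
the result deterministic. Every retained pair ends with |r| at or below
the threshold and the operation is idempotent.

A note on constructing test cases: a correlation chain with both links at
0.95 cannot have an arbitrarily low end-to-end correlation — positive
semidefiniteness forces `r(A, C) >= 2 * 0.95^2 - 1`. The unit tests use a
feasible chain (links ~0.95, ends 0.82).

The univariate screen is the two-sided Wilcoxon–Mann–Whitney test per
retained feature (exact when both groups have at most 25 observations and
no ties; otherwise normal approximation with tie and continuity
corrections). No multiple-testing correction is applied by default;
instead the report compares the observed significant count with the
expected type-I count `m * alpha`, and a Benjamini–Hochberg option exists.

Two statistical caveats are documented rather than hidden:

* **Per-image testing.** The outcome is a patient property but tests run
  per image; multiple images per patient make observations dependent in
  general. In the generator, images are conditionally independent given the
  class, so the null calibration target is exact — real data would need a
  patient-level summary or a clustered test.
* **Machine heterogeneity.** A patient's images share a scanner. Pooling
  machines couples any label assignment with inter-machine feature shifts,
  which inflates the per-image test's size under the null (empirically
  ~0.22 instead of 0.05 at 40 patients with the default four-machine mix).
  This is why the analysis is also run per machine, and why the null-size
  calibration (`null_rejection_rate()`) uses a machine-homogeneous cohort,
  where the empirical rate matches the nominal level within Monte-Carlo
  error.

## Classification strategies

All four strategies share the same hygiene: the 75/25 split and the 5-fold
CV are by *patient*, stratified by label (grouping inside CV is stricter
than a plain row split and honors the same leakage rationale as the outer
split); the positive class is "carrier"; the decision rule is
`score >= cutoff`, with the cutoff chosen on training scores at the maximum
Youden index `J = Se + Sp - 1` (ties to the lowest threshold).

* **A (logistic) and B (RBF-SVM)** use a forward selection wrapper: at each
  step every candidate one-feature extension is fitted, scored by the
  Cohen's kappa of its training confusion matrix at its own Youden-optimal
  cutoff, and the best is kept; the loop stops when kappa no longer
  strictly increases. Kappa ties go to the earlier feature in catalog
  order. Kappa is used instead of accuracy to keep the criterion honest
  under class imbalance. SVM hyperparameters: cost 1, bandwidth `1/p` on
  features standardized by training statistics (the usual pooled-variance
  default); logistic scores are unpenalized maximum-likelihood fitted
  probabilities.
* **C (gradient-boosted trees)** grid-searches depth {2,3,4} x learning
  rate {0.05,0.1,0.3} x trees {50,100,200} x subsample {0.7,1.0} by
  patient-grouped 5-fold CV misclassification error, refits the argmin
  (first in grid order on ties), and reports per-feature total split gain.
* **D (genetic pipeline search)** evolves (preprocessor, model family,
  hyperparameter) genomes — models: logistic, RBF-SVM, boosted trees,
  random forest — with tournament selection, uniform crossover, per-gene
  mutation and single-genome elitism, minimizing the same grouped CV
  error. The defaults (population 24, 8 generations) are a deliberately
  small search: the full automated-ML systems this emulates explore far
  larger operator sets; what is preserved is the defined computation — a
  genetic algorithm over pipelines scored by grouped 5-fold CV error.

Determinism: every stochastic stage (cohort simulation, splits, folds,
subsampling, the GA) is a pure function of its seed; identical
configurations reproduce byte-identical reports.

## What the tests establish

* Matrix builders (GLCM/GLRLM/GLSZM/GLDZM) and the box-counting estimator
  agree exactly with brute-force enumeration on hand grids; conservation
  laws (runs and zones partition the ROI pixel count) and rotation
  coherence (90-degree rotation permutes directional run-length features
  and fixes direction-averaged co-occurrence features) hold on random
  grids.
* With `effect_size = 0` the screen's rejection rate matches its nominal
  level within Monte-Carlo error on a machine-homogeneous cohort.
* With `effect_size = 2`, the planted short-run/high-grey-level signature
  is recovered: the univariate screen flags it with the carrier median
  higher; forward selection picks the planted feature first in at least
  90 % of 25 replicate seeds against 20 noise features; boosted-tree gain
  ranks it top with at least a 1.5x margin; and all four strategies beat
  the majority-class rate on held-out patients.
* No patient ever spans the train/test split or two CV folds.

None of this demonstrates performance on clinical ultrasound; it
demonstrates that the pipeline computes what it claims to compute and can
find a known effect of the kind reported for real cohorts.
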