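---
title: "Severity grading of brain images: models, parameters, and design choices"
author: "mrigrade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity grading of brain images: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrigrade)
```

## The problem

Dementia progression leaves two coarse morphological traces on axial brain
images: the ventricles enlarge and the cortical ribbon thins. `mrigrade`
grades 2-D grayscale brain images into four ordered severity classes
(Non-Demented, Very Mild, Mild, Moderate) with two complementary pipelines:

1. a **hand-crafted feature pipeline** — 12 texture and shape extractors
   producing 90 scalar features per image, compressed by PCA and fed to six
   classical classifiers; and
2. a **compact 20-layer CNN** trained directly on the pixels.

A seeded phantom generator emulates the class structure of a real
severity-graded MRI collection so everything can be exercised, tested, and
benchmarked without clinical data.

## The feature model

Each image is a matrix of intensities in `[0, 1]`. The default 90-feature
vector decomposes as:

| extractor | features | what it measures |
|---|---|---|
| GLCM statistics | 20 | contrast, correlation, energy, homogeneity, entropy of the gray-level co-occurrence matrix at 4 distance-1 offsets (8 gray levels) |
| LBP histogram | 10 | rotation-invariant uniform local binary patterns, radius 1, 8 samples |
| Radial LBP | 10 | LBP where each angular sample is the mean over radii 1..3 before thresholding |
| LTP histograms | 10 | local ternary patterns (tolerance t = 0.1), upper/lower planes, uniform bins merged pairwise to 5 + 5 |
| Region metrics | 16 | area, centroid, convexity, moment-ellipse axes, Euler number, perimeter, solidity, bounding box of the segmented object |
| BIBS signature | 8 | normalized centroid-to-outermost-boundary distances along 8 rays |
| Gabor bank | 8 | mean response magnitude at f ∈ {0.1, 0.25} cycles/px × 4 orientations, σ = 2, 15×15 kernels, unit L2 norm |
| Log-energy | 4 | summed successive differences of mean log-magnitude Fourier spectra of Haar subbands over 2 levels |
| PCA filter | 1 | mean absolute first-principal-component score of 8×8 tiles |
| ICA filter | 1 | mean absolute activation of one FastICA component of the same tiles |
| Fractal dimension | 1 | box-counting slope of the segmented object |
| Shape signature | 1 | aspect ratio of the boundary's bounding box |

The per-extractor budget is this package's allocation; only the total (90)
is fixed by the feature registry, and every block can be disabled through
`feature_config()`.

### Numerical choices worth knowing

* **LBP/LTP tie-breaking.** A neighbour counts as "≥ centre" when
  `neighbour - centre >= -1e-9`. Bilinear interpolation of a perfectly flat
  patch can differ from the centre by floating-point round-off; without the
  slack, codes on constant regions would depend on summation order. The
  brute-force oracles in the test suite implement the same documented rule.
* **Quantization.** Gray levels use equal-width bins on `[0, 1]` with the
  top bin closed, so intensity 1.0 is valid input.
* **Log-energy stabiliser.** The Haar detail subbands of flat regions are
  exactly zero, where `log(abs(.))` is `-Inf`; an `epsilon = 1e-12` inside
  the logarithm keeps the features finite. Level 1 yields an all-zero
  feature block by construction (a difference of a length-1 sequence is
  empty), which the tests pin down.
* **Segmentation.** The shape extractors need a binary object, and no
  segmentation rule is canonical for this: the package uses Otsu's threshold
  on a 256-bin histogram (object = brighter side) followed by keeping the
  largest 8-connected component. Euler numbers pair 8-connected objects
  with 4-connected background. Perimeter is the step count of the Moore
  contour walk — simple and oracle-checkable, with no Crofton correction.
* **Convex area** uses pixel *corner* points, so a solid n×n square has
  convex area exactly n² and solidity exactly 1.
* **Degenerate images.** A constant image has no segmentable object; the
  extractor fails with the extractor named. Non-finite values from any
  extractor are substituted by 0 with a warning so batch runs survive
  single degenerate images.

## PCA reduction

Features mix wildly different units (pixel counts, histogram masses,
radians), so columns are z-scored before the eigendecomposition of the
sample covariance (zero-variance columns get scale 1). Components are kept
up to the smallest k whose normalized cumulative sum of eigenvalues (NCSE)
reaches the threshold; the default 0.999 treats a printed "100%" on a
cumulative-variance curve as float roundoff. The retained k is
data-dependent by design and is not asserted to any fixed value. Loadings
have deterministic signs (largest-magnitude entry positive) so that fits
are reproducible across platforms.

## Classical classifiers

Six families share one fit/predict surface (`severity_classifier` S3
objects; `predict(m, X)` gives labels, `predict(m, X, type = "score")` a
row-stochastic score matrix):

* **Decision tree** with the CART *twoing* criterion
  `(P_L P_R / 4) (Σ_c |p(c|L) − p(c|R)|)²` (gini optional), midpoint
  thresholds, best-first growth capped by `max_splits`, majority leaves
  with ties to the lowest label. Observation weights are supported so the
  same tree is the boosting weak learner.
* **KNN** with correlation distance `1 − r` (constant vectors are defined
  to be at distance 1 from everything — avoids NaN); distance ties break
  towards the lower training index, vote ties towards the lowest label.
* **LDA** with pooled covariance and a ridge of `1e-6·trace/d`, so
  duplicated features do not make the fit singular.
* **Gaussian naive Bayes** with per-class variances floored at `1e-9`.
* **Linear SVM** via `e1071::svm` (one-vs-one, `scale = FALSE` so the
  `C → C/s²` feature-scaling equivalence holds exactly).
* **Ensembles**: bagging, multiclass AdaBoost (the discrete SAMME variant —
  the multiclass flavour is this package's choice), and RUSBoost, which
  undersamples every class to the minority count before each boosting
  round while updating SAMME weights on the full sample.

`optimize_hyperparameters()` runs a seeded random search over documented
per-family grids, scored by 5-fold stratified cross-validated
misclassification (the CV protocol is this package's choice). Infeasible
candidates (e.g. k larger than a fold) score `Inf` rather than aborting the
search.

## The CNN

`build_architecture()` produces exactly 20 layers: input; three
`conv(3×3) → batchnorm → ReLU → maxpool(2×2/2)` blocks with 8/16/32
filters; a fourth `conv(3×3, 64) → batchnorm → ReLU` block; dropout 0.5; a
4-way fully-connected layer; softmax; classification output. That is 4
convolutional, 4 normalization, 4 activation and 3 pooling layers.
Filter counts, the 3×3 kernels, 2×2/stride-2 pooling, SGD with learning
rate 0.01 and batch size 10 are this package's minimal settings — the layer
census is structural, the sizes are not.

Training is plain mini-batch SGD on the softmax cross-entropy, implemented
on base R arrays: convolutions are im2col index gathers followed by BLAS
matrix multiplies, which keeps a 200-image training run in the minutes
range on one CPU. "Normalization" is realised as batch normalization
(running statistics, momentum 0.1, used at inference). All stochastic
steps — the internal stratified split, He-style weight init, shuffling,
dropout masks — derive from one seed, so the first-epoch loss is bit-for-bit
reproducible. Per-epoch curves report the mean batch loss and the
*evaluation-mode* training accuracy (dropout off, running statistics), and
`stop_at_accuracy` allows early stopping once training accuracy converges.

## The phantom generator

`generate_phantom()` draws a bright elliptical "brain" (semi-axes 0.40 and
0.33 of the image), a mid-gray cortical rim, and a dark central "ventricle"
ellipse, plus clipped additive Gaussian noise. Severity acts through the
two markers only: the ventricle scale grows (0.12/0.20/0.30/0.42 of the
brain axis) and the rim thins (7/5.5/4/2.5 px at the 64-px reference size) —
both strictly monotone across the four classes. `generate_dataset()` adds
per-image jitter (centre ±5% of the size, rotation ≤ 10°, scale ±10%) from
one seeded stream. The default noise (`noise_sd = 0.05`) was chosen once so
that classes are learnable but not trivially separable for the classical
classifiers.

What the phantoms deliberately do **not** model: scanner physics, bias
fields, partial-volume contrast, anatomical variability beyond the affine
jitter, or any real MRI texture. Passing benchmarks on phantoms therefore
demonstrates that the pipeline's machinery is correct and that it can
recover a known morphological signal; it says nothing about accuracy on
clinical images, and the package makes no such claim.

## Problem sizes used in tests and the benchmark script

The test suite works at deliberately small scales: oracle equivalence on
16×16 random images, classifier checks on a few hundred synthetic points,
CNN overfitting on 40 phantoms at 32×32, and an end-to-end benchmark of 200
phantoms at 64×64 (70/30 split for the classical methods; the CNN is
trained on all 200 and judged on training accuracy, which it reaches at
1.0, typically within a handful of epochs). `scripts/acceptance.R`
regenerates the 200-phantom benchmark from a command-line seed and records
the CNN's final training accuracy. These sizes are the package's chosen
benchmark conditions, kept small enough to iterate on quickly.

## Known limitations

* Shape features describe a single dominant object; multi-object scenes
  lose everything but the largest component.
* The contour-step perimeter underestimates diagonal boundaries relative
  to Crofton-corrected estimators.
* The twoing tree search is exact over midpoints of observed values but
  greedy over nodes; it makes no optimality claim beyond each split.
* The CNN is CPU-bound base R; it is sized for method validation, not for
  training on thousands of full-resolution images.
* RLBP follows the radial-mean reading of its one-sentence description in
  the literature; other constructions exist under the same name.
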