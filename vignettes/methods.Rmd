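---
title: "Methods: automated liver-tumor annotation at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated liver-tumor annotation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hepannot)
```

## The annotation problem

A liver-cancer diagnosis report records, for every lesion visible in a CT
study, at least three quantities: where the lesion sits (which of the eight
Couinaud segments), how large it is (longest diameter, in centimetres), and
what it looks like (a set of binary radiologic characteristics such as
hypodensity or rim enhancement). `hepannot` implements the full automated
pipeline that produces such a report from a CT volume:

1. **Liver segmentation** — a plain encoder/decoder U-Net with flip
   augmentation.
2. **Tumor segmentation** — a multi-residual attention U-Net (MRAU-Net)
   applied to the liver-masked volume, so the tumor search space is
   restricted to the organ ("segment the liver, then the tumor from the
   liver").
3. **Post-processing** — the thresholded tumor probability map is cleaned
   by closing-then-opening with a disk of radius 1, applied slice-wise in
   the xy, xz and yz planes; a voxel survives if it is positive in at
   least 2 of the 3 plane-wise results.
4. **Couinaud partition** — eight *independent* binary segmentation
   models, one per segment, merged by argmax (ties to the lowest label)
   with a nearest-label fill; the rationale for splitting one 8-class
   problem into eight binary ones is that each model works in a much
   smaller visual space.
5. **Measuring** — the longest Euclidean distance between tumor border
   points, converted to centimetres by the linear regression
   `size = b + a * length` with published coefficients
   `a = 0.0748` cm/px and `b = -0.2011` cm.
6. **Location** — segment `k` is reported when strictly more than 25% of
   the tumor volume lies inside it; if no segment passes, the single best
   segment is reported so a tumor always has a location.
7. **Recognition** — 1316 radiomics features per tumor, univariate feature
   selection (information gain or absolute Pearson correlation), and one
   binary classifier per characteristic (binary relevance; SVM and random
   forest are the recommended bases).

All stages are exercised end-to-end on a synthetic CT phantom, so the
package is fully testable on one CPU with no external data.

## Loss and metrics

Segmentation networks are trained on a weighted combination of three
terms: `w_dice (1 - softDice) + w_bce mean(BCE) + w_mcc (1 - softMCC)/2`.
The soft variants substitute per-voxel probabilities for hard counts, which
keeps every term differentiable. The weighting and reduction are design
choices: defaults are (1, 1, 1), and the MCC term is divided by 2 to map
its `[-1, 1]` range onto `[0, 1]` so the three terms have comparable
magnitude. Degenerate conventions: Dice of two empty masks is 1; MCC with
a zero denominator is 0; probabilities are clipped to `[1e-7, 1 - 1e-7]`
inside the cross-entropy.

Evaluation uses Dice for segmentation (reported per volume and as the
per-case mean — published work rarely states which; we compute both), MAE
and RMSE for sizes, micro-averaged precision/recall/accuracy over the
8-way segment decisions for location, and *example-based* multi-label
metrics for recognition: precision, recall and F1 are computed per record
and then averaged, with a record whose true and predicted label sets are
both empty contributing 1.

## The networks and the autodiff engine

No automatic-differentiation stack is available to this package's R
dependency set, and the networks are part of the contribution, so
`hepannot` ships a small reverse-mode engine of its own (`R/autodiff.R`).
Feature maps are dense arrays with the channel last; convolutions are
im2col gathers followed by one BLAS matrix multiply, and the gradient with
respect to the input is itself a convolution with the spatially flipped,
channel-transposed kernel, so both directions ride on BLAS. The engine
supports exactly the operations the four architectures need (stride-1
same-padded convolutions, 2x transposed convolutions, 2x max pooling,
channel-wise batch normalization, dense layers, the attention gates and
the loss). Every operation is verified against central finite differences
in the test suite, including one end-to-end check through a full MRAU-Net.

Architectural choices that the published figures leave open were fixed as
follows and are exposed in `net_config()`:

* **Multi-residual block** — two chained weighted-identity sub-units:
  `r1 = ReLU(conv3x3(x) + W1 x)` and `y = ReLU(SE(conv3x3(r1)) + W2 r1)`,
  with `W1`, `W2` 1x1-convolution linear mappings. Whether the
  squeeze-and-excitation gate sits on the second convolution's output
  before the addition (default, `se_position = "pre_add"`) or after the
  final ReLU cannot be read from the source figure; it is a configuration
  switch.
* **SE bottleneck** — reduction 16, clamped to the channel count.
* **Pixel-wise attention** — `alpha = sigmoid(conv1x1(ReLU(L1(skip) +
  L2(gate))))` with `L1`, `L2` 3x3 convolutions; the gated skip is
  concatenated with the upsampled decoder path.
* **Downsampling** — 2x2 max pooling between encoder blocks, matching the
  3-D description; 4 encoder levels plus a bottleneck by default, so input
  sizes must be divisible by 16.
* **3-D variant** — batch normalization + LeakyReLU on every convolution,
  3x3x3 kernels, 2x2x2 pooling and transposed convolutions, 1x1x1 sigmoid
  head. With one volume per gradient step the batch statistics reduce to
  per-channel spatial statistics; running means/variances are kept for
  inference.
* **Input channels** — single channel (one slice / one volume); no 2.5-D
  stacking.
* **Optimization** — Adam at 1e-3, batch 4, He initialization from a
  per-network seed; training histories are bit-reproducible given the
  seed.

Desk-scale defaults (base 32 filters; 16 for the overfit protocol; 4 for
the coarse 3-D partition models) were chosen so every training protocol in
the test suite runs in minutes on one CPU. They are configuration, not
architecture.

### Partition models and coordinate channels

The eight per-segment models receive the liver-masked intensity plus three
normalized coordinate channels. The pseudo-Couinaud compartments are
defined by position within the organ, which a translation-invariant
convolutional network cannot recover from intensity alone; coordinate
channels make the task well-posed (the classic CoordConv argument). Both
training and prediction crop to the liver bounding box (padded to the
pooling multiple): this keeps the coordinate channels consistent between
the two paths and roughly quadruples the foreground fraction, which
stabilizes the Dice term early in training.

## The phantom generator

The generator (`make_phantom()`) emulates the aspects of contrast CT that
the pipeline actually consumes:

* a smooth convex super-ellipsoid "liver" (intensity ~100 against a ~20
  background, plus a low-frequency parenchyma field, amplitude 8);
* an 8-compartment partition obtained by splitting the liver support at
  its per-axis median planes — contiguous, non-empty, plane-based
  compartments standing in for the vascular Couinaud geometry (the
  pipeline under test never uses vessel anatomy);
* ellipsoidal tumors with the major axis in-plane (the axial in-plane
  diameter is what the measuring stage reads, mirroring how lesions are
  measured on axial slices), drawn from 1-5 cm — the range most liver
  lesions fall in;
* additive Gaussian noise (sd 3) on the final volume;
* default grid 64 x 96 x 96 at (2.5, 1, 1) mm — thick-slice CT geometry at
  a size where a full pipeline run takes minutes.

Each tumor carries 11 binary characteristic labels, each a fixed threshold
on one generative parameter: intensity offset sign (hypodense), margin
lobe depth (irregular margin), blob-mixture amplitude (heterogeneous),
diameter > 3 cm (large), sorted second/first and third/first axis ratios
(elongated, flattened), a bright 0.8-1.0 shell (rim enhancing), core noise
sd (noisy core), the wavelength of a fixed-amplitude in-plane grain
(coarse texture), absolute offset (strong contrast), and small bright
nodules (focal inclusions). Three design rules make these labels
well-posed rather than easy:

* every labelled attribute must be *visible at the phantom's resolution* —
  margin lobes live in the axial plane where spacing is 1 mm, the grain
  has no z variation (2.5 mm slices would alias it), and the z semi-axis
  is constrained shortest so the sorted PCA axis ratios map one-to-one to
  the generating ratios;
* continuous parameters are drawn with a narrow exclusion band around the
  label cut, so labels are deterministic attributes, not coin flips at the
  threshold;
* cut points sit at the sampling median, giving cohort prevalences near
  0.5 (cohorts of 30+ verify every prevalence lies in [0.2, 0.8] and
  re-draw otherwise).

What the phantom does **not** emulate: vascular anatomy and vessel-based
partition geometry, Hounsfield calibration, partial-volume and beam-
hardening artifacts, respiratory motion, and the correlation structure of
real lesion appearance. Passing tests therefore demonstrate that the
pipeline's machinery is correct and that its statistical stages recover
known signal at realistic contrast and noise — not clinical performance.
The margin-irregularity label remains the hardest in practice: its shape
signal is partially confounded with the axis ratios (partial correlation
about -0.7 behind the marginal -0.4), and per-label accuracy stays near
chance at a 30-case cohort; the example-based criteria are met by the
other ten labels.

## Measuring

`longest_diameter()` defaults to the per-slice 2-D reading: the maximum
pairwise Euclidean distance between border pixels within an axial slice,
maximized over slices, in pixel units. The published slope of 0.0748 cm/px
corresponds to a ~0.75 mm in-plane pixel, which identifies the regression's
`length` as an in-plane pixel distance; a `volume3d` mode over 3-D border
voxels is provided for spacing-aware cross-checks. The farthest pair is
found exactly: border voxels are pruned to per-slice convex-hull vertices
(every extreme point of the 3-D cloud is a 2-D hull vertex of its slice)
and the reduced set is searched in blocked matrix arithmetic; tests verify
equality with brute-force all-pairs search. Negative regression outputs
(possible below ~2.7 px) are clamped to zero only in the final report,
with a warning.

On phantoms the regression is calibrated on ground-truth masks of half the
cohort and evaluated on the other half (the 2-fold protocol used for
measuring); the in-plane pixel is 1 mm there, so the fitted slope is ~0.1
cm/px rather than the published 0.0748, which belongs to the source data's
pixel grid.

## Post-processing

The published description names an integer threshold (2) and three planes
(xy, xz, yz). The only reading under which those interact is a plane-vote:
clean the thresholded mask independently per plane (closing then opening,
disk radius 1), then keep voxels positive in at least 2 of 3 results. The
vote threshold, structuring radius and operation order are configurable so
alternative readings can be tested; vote monotonicity (result at threshold
3 contained in 2 contained in 1) is a tested invariant.

## Location rule

The published overlap rule ratios *predicted* against *ground-truth*
segments — an evaluation framing that cannot run online, where no ground
truth exists. Operationally the rule is read as tumor-fraction-per-segment:
include segment `k` when `|tumor ∩ segment_k| / |tumor| > 0.25` (strict).
The evaluation form survives in `location_accuracy()`. The strictness at
exactly 25% is honored and tested; a tumor that passes nowhere reports its
single best segment, because a lesion inside the liver must have a
location.

## Recognition

The default radiomics configuration is pinned by its dimensionality: 107
features on the original image (14 shape + 18 first-order + 24 GLCM + 16
GLRLM + 16 GLSZM + 14 GLDM + 5 NGTDM) plus the 93 non-shape features on
each of 5 Laplacian-of-Gaussian scales (1-5 mm) and 8 single-level Haar
wavelet bands, i.e. 107 + 5x93 + 8x93 = 1316 per tumor — the unique small
decomposition consistent with the published total and standard catalogs.
Implementation choices: undecimated Haar bands (so masks need no
resampling), scale-normalized LoG, gray levels binned at width 5 anchored
at the masked minimum (widened to cap 64 levels), texture matrices
accumulated over the 13 unique 3-D directions, surface area by the coarea
formula on a smoothed indicator (voxel-face counting overestimates by a
staircase factor), and PCA axis lengths from physical voxel coordinates.
Values match the *catalog definitions*, not any particular external
implementation bit-for-bit.

Feature selection is univariate per label: information gain after a
median split (two bins — IG needs a discretization and the source does not
state one), or absolute Pearson correlation; ties break by column order,
and zero-variance columns score 0. Classification is binary relevance —
one base classifier per label — with SVM (radial), random forest, LDA,
a single-hidden-layer neural network and XGBoost as bases; AdaBoost is not
offered because no suitable implementation is available to the package.
`train_multilabel()` keeps 50 features per label by default; the
phantom-cohort protocols use `k = 10`, because 24 training rows cannot
support 50-dimensional fits — with ~1300 candidates and a handful of
truly informative columns, selection noise at `k = 50` measurably hurts
both bases. Cross-validation is 5-fold with selection redone inside every
fold, and a stratified-random baseline (per-label Bernoulli at empirical
prevalence) anchors chance level.

## Problem sizes used by the test and acceptance protocols

* overfit oracle: one 64x64 liver-masked slice, MRAU-Net base 16, 200
  epochs (~1.5 min);
* partition oracle: six 16x32x32 phantoms, eight 3-D U-Nets (depth 2,
  base 4, coordinate channels), 30 epochs (~4 min) — per-segment mean
  Dice >= 0.8, seed-pinned;
* recognition: 30-case default-geometry cohort, 1316 features per tumor
  (~2 min extraction), 5-fold CV with SVM and RF;
* measuring: same cohort, 2-fold calibration on ground-truth masks.

These sizes are the package's desk-scale study conditions; they were
chosen once so the full suite runs in well under half an hour on a single
CPU, and the seeds printed in the tests freeze them.

## Known limitations

* Training at these sizes demonstrates optimization correctness and
  architecture behavior, not segmentation accuracy on clinical data; the
  published cohort-scale results (LiTS, MedSeg, hospital data) are out of
  desk-scale reach by design.
* The autodiff engine is single-threaded R + BLAS; it is not a general
  deep-learning framework (no dilation, no strided convolutions other
  than 2x, no GPU).
* Radiomics values follow the standard definitions but are not calibrated
  against any external implementation; analyses should treat them as
  internally consistent features rather than interchange values.
* The phantom's plane-based compartments make the partition task easier
  than vascular Couinaud anatomy; the 8-model machinery, merge rule and
  location rule are what is being validated.
* The tri-planar opening imposes an effective minimum lesion thickness:
  a tumor spanning fewer than ~3 slices is erased by the xz/yz plane
  openings and disappears from the report (at 2.5 mm slices this is
  roughly the 1-1.5 cm regime). This is a faithful consequence of the
  published post-process on anisotropic voxels, surfaced by the phantom.
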