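---
title: "Detecting cone photoreceptors with a patch-based CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cone photoreceptors with a patch-based CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Adaptive-optics scanning light ophthalmoscopy (AOSLO) resolves individual
cone photoreceptors in the living human retina. Quantifying the cone mosaic
— counts, density, spacing — requires the coordinates of every cone in an
image, and manual grading is slow and subjective. `conefinder` implements a
learning-based detector: a small convolutional neural network classifies the
33×33-pixel patch around every pixel as cone-centred or not, and simple
morphological post-processing turns the resulting probability map into cone
coordinates. Because the features are learned from marked training images,
the same algorithm serves confocal AOSLO (cones appear as bright blobs) and
split-detector AOSLO (cones appear as horizontal bright/dark dipoles): only
the training data changes.

## Training data construction

Each training image is min–max normalized to [0, 255] (`normalize_intensity()`;
a constant image maps to all zeros, the conservative choice for a degenerate
input). Cone patches are extracted at every manual mark, rounded to the
nearest pixel since patches are pixel-aligned. Non-cone locations are not
marked by graders, so they are synthesized geometrically: the manual marks
generate a Voronoi tessellation, whose edges run along the gaps between
cones, and one point is sampled per edge.

Design choices the construction leaves open, and what this package does:

* **Sampling distribution along an edge** — uniform in arc length over the
  finite (clipped) segment; the natural reading of "random point on an
  edge".
* **Unbounded ridges** — clipped at the image rectangle and kept when the
  clipped portion has positive length.
* **Sub-pixel edges** — an edge shorter than one pixel contributes its
  rounded midpoint.
* **Duplicates** — two edges can round to the same pixel; duplicates are
  dropped because identical patches add no information and silently bias
  the class ratio.
* Patches that would cross the image border are excluded (both classes), so
  every patch is a clean 33×33 crop.

The Voronoi edges themselves are computed by exact half-plane intersection
along each cone pair's perpendicular bisector (O(n³) in the number of cones)
rather than by a sweep-line library; at the ~100 cones of a typical region
of interest this costs milliseconds and gives the clipped finite edges
directly, with each edge's two generating cones attached.

## The classifier

The network is deliberately small (a CIFAR-style stack):

| stage | operation | output |
|---|---|---|
| 1 | conv 5×5×1→32, stride 1, pad 2 | 33×33×32 |
| 2–4 | batch norm, max-pool 3×3/2, ReLU | 16×16×32 |
| 5–8 | conv 5×5×32→32, bn, ReLU, avg-pool 3×3/2 | 8×8×32 |
| 9–12 | conv 5×5×32→64, bn, ReLU, avg-pool 3×3/2 | 4×4×64 |
| 13–15 | fully connected →64, bn, ReLU | 64 |
| 16–17 | fully connected →2, soft-max | 2 |

The printed sizes are the contract; since 5×5 convolutions preserve spatial
size, they use zero padding 2, and the stride-2 pools append one trailing
zero-pad row/column when `(H-3)` is odd (16→8 and 8→4) so that every input
pixel is covered. Average pooling divides by the full 3×3 window including
padding; max pooling ignores padding.

Training is plain SGD with back-propagation: mini-batches of 100 patches,
per-epoch reshuffling, 45 epochs by default with all learning rates divided
by 10 entering epochs 31 and 41. Weight learning rate 0.001 and bias
learning rate 0.1, except the final fully connected layer (0.0001 / 0.01);
weight decay 0.0001 on convolution/FC weights. Choices the schedule leaves
open:

* **Initialisation** — zero-mean Gaussian weights, SD 0.01 (`init_sd`),
  zero biases; the era-appropriate toolbox default. Exposed in
  `cnn_config()` because small CNNs are initialisation-sensitive.
* **Momentum** — 0.9 by default (the training-toolbox default of the era);
  set `momentum = 0` for the strict textbook reading.
* **Batch norm** — ε = 1e-5. Running statistics are tracked as exponential
  moving averages (weight 0.1) during training, and the inference
  statistics are then recomputed as exact population moments over the
  training set with the final weights (one sweep per batch-norm layer,
  since each layer's input depends on the finalized statistics of the
  layers before it). The moving averages alone need a few hundred steps to
  converge and would make short training runs unreliable at inference.
  The learnable scale and shift train at the weight learning rate (the 0.1
  bias rate applies to convolution/FC biases only, matching the era's
  toolbox convention).
* **Class imbalance** — the Voronoi construction yields roughly 2.5 non-cone
  patches per cone patch; no reweighting is applied.
* Patches enter the network on the 0–255 scale; no per-patch
  standardisation, since the first batch-norm layer absorbs the scale.

Everything is seeded: initialisation and batch shuffling derive from
`cnn_config(seed = )`, and a fixed seed reproduces the final weights
bit-for-bit on a single thread.

## From probability map to cones

`compute_probability_map()` classifies the patch around every pixel; pixels
within 16 px of the border get patches completed by half-sample mirror
reflection (the edge pixel is duplicated). The map is then

1. smoothed with a Gaussian of standard deviation σ (kernel truncated at
   4σ, edge-duplicating boundary);
2. binarised with the extended-maxima transform of height H — the regional
   maxima of the H-maxima transform, computed by grayscale morphological
   reconstruction with 8-connectivity, which suppresses peaks standing less
   than H above their surroundings;
3. cleaned by removing any 8-connected cluster whose maximum smoothed
   probability is below T;
4. reduced to one cone per surviving cluster at the unweighted centroid of
   its pixels (fractional coordinates; a probability-weighted centroid is
   available via `weighted = TRUE` but is not the default, matching the
   simplest reading of a cluster "centre").

The reconstruction uses the hybrid raster/queue algorithm; the test suite
checks it for exact agreement against a brute-force iterative geodesic
dilation oracle, including plateau and constant-image cases, since this is
the most delicate correctness surface in the pipeline.

For speed, whole-image inference folds each inference-mode batch-norm layer
(an affine map per channel) into the preceding convolution/FC weights and
runs in a single compiled pass with GEMM-based convolutions. This is an
algebraic identity: the map agrees with patch-by-patch classification to
floating-point rounding, which the tests assert at 1e-6.

## Automatic parameter selection

(σ, H, T) are chosen by exhaustive grid search maximising the mean
per-image Dice coefficient of detections against the manual marks over
training images, with probability maps computed once and reused
(`optimize_params()`). The default grid is σ ∈ {0, 0.1, …, 3.0},
H ∈ {0, 0.05, …, 0.5}, T ∈ {0.1, …, 0.9}, chosen so that the published
optima for confocal (1.3, 0, 0.3), split-detector (2, 0.1, 0.5) and
mixed-modality (0.4, 0.25, 0.9) detection are all exact grid points; grid
values are built by integer division to avoid floating-point drift. Ties
are broken towards the smallest σ, then smallest H, then largest T —
preferring the least smoothing and suppression that achieves the best
score.

## Matching and metrics

Automatic cones are matched one-to-one to manual cones: both sets are first
pruned of points within 7 px of any image edge (border artifacts), then
candidate pairs within the match radius d are accepted greedily in
ascending distance order, so that when several detections fall near one
manual cone only the closest becomes the true positive. The radius is
d = 0.75 × the median over cones of the nearest-neighbour distance among
manual marks — "spacing" is not otherwise defined, and the median NN
distance is the standard mosaic spacing statistic. Exact distance ties
break by lower manual index for determinism. The greedy rule is validated
against a maximum-cardinality assignment oracle on small random instances.

From the counts: true positive rate TP/N_manual, false discovery rate
FP/N_automatic, Dice 2·TP/(N_manual + N_automatic); a metric with a zero
denominator is reported as `NA`, never silently 0. Cone density is
count/area with area from the image's micron-per-pixel scale; by default
the full pixel area is used and no border pruning is applied
(`cone_density(border = , prune_area = )` expose the alternatives).
Bland–Altman agreement is the mean difference with 95% limits at
±1.96 sample SD.

## The synthetic mosaic generator

`generate_mosaic()` renders what the detector needs to be exercised
end-to-end with exact ground truth: cone centres on a hexagonal lattice
(cone mosaics are quasi-hexagonal) with random phase, i.i.d. Gaussian
positional jitter (SD 1 px), and 10% random dropout; about 100 cones on a
150×150 px field at lattice constant 14 px, matching a typical region of
interest. Confocal appearance is a sum of isotropic Gaussian blobs
(amplitude ~N(150, 20²), radius ~N(2.2, 0.2²) px) over background 30;
split-detector appearance is a horizontal first-derivative-of-Gaussian
dipole (bright left lobe, dark right lobe, zero crossing at the cone
centre). Both add a smooth low-frequency background field (three random
long-wavelength sinusoids) and white Gaussian noise (SD 8).

What the generator does **not** emulate: AOSLO point-spread and scanning
optics, speckle/Poisson statistics, rods and vasculature shadows, motion
artifacts, eccentricity gradients in cone size and spacing, and pathology.
Passing the fixture pipeline therefore demonstrates that the
implementation is correct and the method recovers a known mosaic under
noise — not that it reproduces performance on real retinas.

## Desk-scale problem sizes

The bundled fixture suite is 20 training + 10 validation mosaics per
modality. The end-to-end runs train the full architecture at reduced
scale — 4 epochs with a learning-rate drop entering epoch 3 — and tune on
the probability map of one training image; the grid search itself is
exhaustive over the full default grid. These sizes are the package's
choice of a desk-scale experiment: on the synthetic mosaics training
accuracy saturates by the third epoch, and the homogeneous generator makes
per-image tuning representative. On real data one would train the full
45-epoch schedule and tune over all training images.

## Known limitations

* No data augmentation or hard-negative mining beyond the Voronoi rule.
* No sub-pixel refinement beyond the cluster centroid, and no non-maximum
  suppression by inter-cone distance.
* The detector is per-modality: applying a confocal-trained network to
  split-detector images requires retraining (or a mixed training set).
* Density requires a per-image scale; images without one skip density and
  Bland–Altman reporting.
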