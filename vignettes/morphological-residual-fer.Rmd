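---
title: "Morphological residual features for facial expression recognition"
author: "morphfer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological residual features for facial expression recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Facial expression recognition (FER) assigns one of seven basic emotion
categories — angry, disgust, fear, happy, neutral, sad, surprise — to a face
image. Appearance-based convolutional networks learn this mapping directly
from pixel intensities, which makes them sensitive to illumination, skin
tone and other appearance factors that carry no expression information.
Expressions, however, are chiefly *geometric*: raised eyebrows, a curved or
opened mouth, widened eyes. This package implements a hybrid in which flat
grayscale mathematical morphology extracts that geometry explicitly, and the
resulting *residual images* are fused, by channel concatenation, into
otherwise standard convolutional classifiers.

For a grayscale image $I_f$ and a flat (binary) structuring element $B$ with
its origin at the center cell, the four base operators are the window
extrema

$$I_d = I_f \oplus B \quad (\text{max}), \qquad
  I_e = I_f \ominus B \quad (\text{min}),$$
$$I_o = (I_f \ominus B) \oplus B \quad (\text{opening}), \qquad
  I_c = (I_f \oplus B) \ominus B \quad (\text{closing}).$$

The residual channels subtract in the direction that keeps them
non-negative:

$$I_{fd} = I_d - I_f, \qquad I_{fc} = I_c - I_f, \qquad
  I_{fe} = I_f - I_e, \qquad I_{fo} = I_f - I_o,$$

i.e. the external and internal morphological gradients and the black and
white top-hats. They respond at intensity edges — eyebrow bars, eyelids,
mouth contours — and vanish on homogeneous regions, which is exactly the
structural information expressions live in.

Three model families are provided:

* **MNN** — a structure-only baseline: a fixed $7\times7$-disk opening, the
  subtraction $I_f - I_o$, a flatten and two dense layers
  ($25{,}600 \to 512 \to 7$; 13,111,303 learnable parameters at the
  160-pixel input side). No convolutions at all.
* **MCNN1** — all four residuals concatenated into a 4-channel input,
  followed by four blocks of [3×3 convolution, batch norm, ReLU, 2×2
  max-pool] with 128/256/512/1024 filters, a small ReLU dense layer
  (16 units) and a 7-way softmax.
* **MCNN2 (v1–v6)** — three-channel inputs pairing the raw image with two
  residuals (v5 = $I_f, I_{fe}, I_{fo}$ and so on), feeding an unchanged
  lightweight depthwise-separable-convolution backbone. Because the
  morphological front-end is fixed, all six variants and the
  replicated-grayscale baseline share one parameter count — the comparison
  isolates the input representation.

The evaluation protocol is subject-independent throughout: k-fold partitions
are made over *subject identifiers*, never samples, so no individual
appears on both sides of any split ("identity leakage"); cross-dataset
generalization is probed by leave-one-dataset-out splits over source
corpora.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| structuring element | disk, 7×7 (29 cells) | neighborhood probed by the morphology; the disk is isotropic, the square favors axis-aligned structure |
| canonical side | 160 px | square model input after grayscale conversion and bicubic resize |
| folds / seed | k = 10, seed 42 | subject-level partition of the catalog |
| optimizer | Adam, lr 1e-5 | study-scale training configuration |
| batch / epochs | 32 / ≤100 | best-validation-accuracy epoch is retained |
| L2 on dense weights | 1e-3 | regularization of the classification head |
| augmentation | flip ½, zoom ≤10 %, shift ≤5 %, brightness 80–120 % | training stream only; rotation deliberately excluded |

The structuring-element *shape* for the residual channels is configurable;
the disk is the default because the dense-only baseline is explicitly
disk-based and no statement forces the square for the hybrid models. Which
of the two shapes the original experiments used is unknowable from the
description; both are available.

## Numerical choices

* **Border handling** is edge replication for the morphological window
  extrema, so constant images are fixed points everywhere and residuals are
  zero including at borders; zero padding would manufacture spurious border
  responses in the feature channels.
* **Disk definition**: cell $(dx, dy)$ active iff $dx^2 + dy^2 \le r^2$,
  $r = (s-1)/2$; 29 active cells at $7\times7$.
* **Residual arithmetic** runs in doubles on the uint8 scale — no integer
  wraparound — and every channel (raw and residual) is rescaled by $1/255$
  uniformly at model input.
* **Grayscale conversion** uses full-range BT.601 luma
  ($0.299R + 0.587G + 0.114B$, rounded half-up); the studio-range variant
  was rejected to keep the full dynamic range.
* **Bicubic resize** is the separable Catmull-Rom kernel ($a=-0.5$) with
  edge clamping, implemented as row/column weight matrices whose rows sum
  to one (constants are exactly preserved). Output is rounded and clipped
  back to uint8, so interpolation overshoot cannot leave the domain.
* **Prediction ties** break toward the lowest class index (alphabetical
  order, "angry" first); max-pool gradient ties route to the first window
  cell; a never-predicted class contributes precision 0 (with a warning)
  to the macro average.
* The macro F1 is the harmonic mean of *macro* precision and *macro*
  recall — not the average of per-class F1 — matching the metric
  definitions the package targets.
* **Fold assignment** deals the seeded-shuffled subject list round-robin
  into k folds: subject counts are balanced to within one. Class
  stratification is not attempted, since the partition unit is the
  identity, not the sample.
* Where a protocol needs validation *and* test subsets (epoch selection
  plus held-out scoring), the held-out fold (or source) is the test stream
  and a configurable fraction (default 15 %) of the remaining subjects is
  carved out for validation — one interpretation of a fold-rotation
  protocol that reports all three figures.

## The network engine

No deep-learning framework is part of this package's dependency set; the
layers it needs are implemented directly in R: 3×3 same-padded convolutions
via im2col + BLAS matrix multiplication, depthwise and pointwise (1×1)
convolutions for the separable backbone, batch normalization (momentum 0.9,
eps 1e-5), 2×2 max-pooling, global average pooling, dense layers, softmax
cross-entropy and Adam. Gradients are verified against central finite
differences in the development process, and training is deterministic given
the seed and a fixed single-threaded BLAS. This keeps every architecture
inspectable — `parameterBreakdown()` reports the per-layer counts that the
bookkeeping identities rest on — at the cost of training speed, which is
why the shipped experiments run at reduced width and input side.

Parameter counting reports learnable weights and biases (convolution and
dense weights/biases, batch-norm scale/offset); batch-norm running
statistics are counted only on request. The dense-only baseline contains no
batch norm, so its headline count is insensitive to that convention.

## The synthetic corpus

Licensed face corpora cannot ship with a package, so every pipeline stage
is exercised on a parametric generator. Each *subject* draws base geometry
(face-ellipse axes, inter-eye distance, feature anchor rows, skin tone);
each *class* has a fixed deformation template (eyebrow angle and raise,
mouth curvature and openness, eye aperture) with per-sample Gaussian
jitter; each *source* adds a skin-intensity offset and a linear
illumination gradient, emulating corpus heterogeneity. Gross face placement
is kept narrow deliberately: a face-crop stage normalizes position and
scale in real pipelines, and identity is carried by proportions instead.

The defaults (30 subjects × 7 classes × 2 images over 3 sources, 160-pixel
canvas, noise sd 4) are the corpus used by the shipped experiments. The
generator guarantees three properties the tests rely on: noiseless renders
are perfectly separated by their class templates (the corpus carries
learnable signal); per-subject geometry makes subject-dependent splits
measurably easier than subject-independent ones (the leakage the protocol
guards against is demonstrable); and source offsets make leave-one-source-out
transfer harder than pooled splits.

What passing on this corpus does **not** show: robustness to pose, occlusion,
texture, demographic variation, or any photometric property of real faces.
The synthetic results validate the machinery — protocol integrity,
architecture bookkeeping, learnability of geometric structure — not
real-world recognition accuracy, and the published accuracies on licensed
corpora are out of this package's reproduction surface by design.

## Scaled-down experiment sizes

The shipped learnability experiment uses the 30-subject corpus above,
preprocessed to a 48-pixel canonical side, with MCNN1 at filters
8/16/32/64 and a 16-unit dense layer, trained 18 epochs with Adam at
learning rate 2e-3 (batch 32, standard augmentation) under a linear
3-epoch learning-rate warmup. A from-scratch CNN at full width, side and
schedule is not informative at these sample sizes; the reduced
configuration reliably exceeds twice the 1/7 chance level on held-out
subjects, which is the property of interest. The larger learning rate
compensates for the short schedule, and the warmup protects against the
early-step collapse into the uniform-prediction saddle that aggressive
rates can otherwise cause at this scale; the study-scale default (1e-5,
100 epochs, no warmup) remains the package default in `trainConfig()`.

## Known limitations

* The custom conv hyperparameters that the original architecture leaves
  unstated (kernel size, padding, pool geometry, head width) are fixed here
  at 3×3 / same / 2×2-stride-2 / 16; printed totals for MCNN1 and the
  MobileNetV2-family backbone are therefore not reproduced and are treated
  as non-normative. The dense-only baseline's count *is* reconstructable
  and is asserted exactly.
* The depthwise-separable backbone is a lightweight stand-in architecture
  of the same family as MobileNetV2 (depthwise + pointwise blocks), not a
  layer-for-layer replica; pretrained ImageNet weights are not available
  offline, and requesting them falls back to random initialization with a
  warning.
* Viola–Jones face detection is a pluggable adapter contract, not a
  re-implementation; the default detector passes the whole frame through.
* Efficiency figures (latency, memory) are hardware-dependent and are
  reported but never asserted.
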