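---
title: "Estimating hemoglobin from eyelid images: model, simulator, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating hemoglobin from eyelid images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palpebral)
```

## The problem

The palpebral conjunctiva — the capillary-rich lining of the everted lower
eyelid — pales as blood hemoglobin (Hb) falls. Clinicians exploit this in
the visual assessment of anemia; this package implements the quantitative
version: regress a patient's Hb concentration (g/dL) from an eye photograph.

Two ideas structure the method.

**Causal region extraction.** Only conjunctival pixels are *causally*
related to Hb: intervening on them changes what an ideal predictor of Hb
would read off the image. Sclera, pupil, lashes, and skin correlate with Hb
in observational data only through the patient (a common cause), so a model
trained on whole images can latch onto spurious signal that fails to
generalize. Stage one therefore restricts the image to the eyelid region
using a binary mask. The package deliberately *consumes* masks — from the
simulator's ground truth, from PNG files, or from any external segmentation
model — rather than bundling a segmentation network: mask application
semantics and mask-quality metrics (AP/AR at IoU thresholds, mIoU) are what
the method needs, and any instance segmenter satisfying the mask contract
can be plugged in.

**Label distribution learning.** Hb labels are continuous, skewed, and
expensive to collect. Instead of one-hot targets or plain scalar
regression, the scalar label \(y\) is encoded as a discrete Gaussian over a
support grid \(k_1 < \dots < k_K\):

\[
p_k(y, \sigma) \;\propto\; \exp\!\left(-\frac{(k - y)^2}{2\sigma^2}\right),
\qquad \sum_k p_k = 1 ,
\]

so neighboring Hb values share training signal. The network ends in a
\(K\)-way softmax \(\hat p(X, \theta)\), trained with the composite loss

\[
\ell \;=\; \underbrace{\textstyle\sum_k p_k \ln (p_k / \hat p_k)}_{KL}
\;+\; \lambda\, \underbrace{|\hat y - y|}_{L1},
\qquad \hat y = \textstyle\sum_k k\, \hat p_k .
\]

The L1 term needs a scalar prediction; we decode by expectation rather than
argmax because the expectation is continuous in the logits (argmax would
quantize predictions to the grid spacing) and is automatically confined to
\([k_1, k_K]\).

## Numerical and design choices

* **Support grid.** The label range is \([6, 18]\) g/dL, the candidate
  range \([5, 20]\), and the output head is 15-way. We reconcile these by
  taking the grid as the 15 centers of equal bins on \([5, 20]\):
  \(5.5, 6.5, \dots, 19.5\), spacing 1.0. Configurable via
  `support_grid()`.
* **Renormalization.** The Gaussian kernel is a density, not a probability
  vector, on a discrete support; we renormalize over the grid because a KL
  divergence against a softmax output is only well-defined between
  probability vectors.
* **σ (label width)** defaults to 1.0 — one grid spacing: wide enough that
  2–3 bins receive appreciable mass (which is the point of sharing signal
  across neighboring labels), narrow enough that the encode/decode round
  trip stays within half a bin for labels away from the grid boundary.
* **λ (KL vs L1 weight)** defaults to 1, treating one nat of divergence as
  exchangeable with one g/dL of absolute error; both terms are exposed.
* **Floors.** Predicted probabilities are floored at \(10^{-12}\) inside
  logarithms; softmax uses max-subtraction. `encode_label` works in log
  space so tiny σ cannot underflow to an all-zero vector.
* **IoU conventions.** Two empty masks score IoU 1 (with a warning);
  exactly one empty mask scores 0. AP here is precision at a threshold —
  the task has one unscored instance per image, so there is no
  confidence-ranked PR curve to integrate.
* **EVS vs R².** Both are reported; they differ exactly by the mean
  residual term, and the test suite asserts their equality on mean-centered
  residuals. Population (1/n) variances are used so that identity is exact.

## The network

The regressor is a compact convolutional network written directly in
vectorized R: stride-2 3×3 convolution + ReLU blocks (im2col gathers
followed by one BLAS matrix product per layer), a squeeze-and-excitation
head — global average pooling, a bottleneck of reduction 4, sigmoid channel
gating — and a linear projection to the 15 logits. The backward pass is
derived analytically per layer; the test suite checks it against central
finite differences to \(10^{-4}\) relative error, which is what makes a
hand-written backward pass trustworthy.

The desk-scale default is 64×64 inputs with 4 blocks (channels 8/16/32/64);
`net_config(input_size = 224, depth = 5)` reproduces the full-scale input
geometry when compute allows. The full-scale protocol this mirrors uses a
MobileNet-class backbone; the package keeps only what that study's
contribution needs — the SE head and the 15-way distributional output — on
a small generic backbone, because the loss and pipeline, not the backbone,
are the subject here.

Optimization follows the reference protocol: SGD with momentum 0.9, weight
decay 5e-4, batch size 64, constant learning rate 0.01, early stopping on
validation MAE. The epoch budget defaults to 80 with patience 15: with a
constant learning rate the desk-scale problem is still descending at epoch
30, and runs typically stop early around epoch 60–80. (The full-scale
protocol budgets 300 epochs with a premature-stop strategy; 80 is the
desk-scale analogue, chosen once from training-curve inspection on the
simulator's default conditions.)

## What the simulator does — and does not — emulate

`generate_dataset()` draws Hb from a normal(12, 2) truncated to \([6, 18]\)
— mid-peaked and thin-tailed, matching the clinical situation where normal
Hb dominates and both extremes are rare — and renders:

* an **eyelid crescent** (everted-lid geometry, randomized center/axes
  ±10%) whose mean red channel is \(110 + 8\,(\mathrm{hb} - 6)\) plus
  noise: the causal signal, linear in the red channel because redness
  ratios are the classical conjunctival correlate of Hb and a linear map
  makes slope-recovery oracles closed-form;
* **distractor regions** (sclera, pupil, lash band, skin) whose red
  channel is shifted by `confound_strength × 6 × (hb − 12)` plus
  independent noise: spurious signal whose informativeness is dialed by
  `confound_strength` in \([0, 1]\);
* region-level and per-pixel Gaussian noise (`noise_sd`, default 6
  intensity units) and a global lighting offset (sd 3).

Ground-truth masks mark exactly the crescent. By construction, mask pixels
predict Hb better than background pixels whenever `confound_strength < 1`,
which is what makes the ablation's direction provable in simulation rather
than merely plausible.

The simulator does **not** model photorealistic anatomy, camera or exposure
physics, skin-tone variation, specular highlights, or motion blur. Passing
tests on simulated data therefore demonstrate that the *pipeline* is
correct and that the *causal-region logic* does what it claims under known
ground truth — not that any particular clinical accuracy would be attained
on real photographs.

## Balancing

Clinical Hb distributions are mid-peaked, so extreme labels are rare.
`smote_balance()` discretizes labels into 1 g/dL bins and up-samples every
non-empty bin to the largest bin's count by SMOTE interpolation between
same-bin nearest neighbors (labels interpolated with the same coefficient);
singleton bins fall back to 1%-jittered duplication. Images are
interpolated in flattened 32×32 pixel space — the simplest faithful reading
of applying SMOTE to images. Balancing the *test* partition, as the
historical protocol did, is supported behind `paper_protocol = TRUE` but
off by default: evaluating on synthetically rebalanced test data inflates
apparent performance on rare labels, and the default is the
methodologically safer choice.

## Problem sizes used by the test suite and acceptance script

Chosen once as desk-scale study conditions: parameter recovery trains on
500 masked images (64×64, noise sd 2, confound 0.5) and evaluates on 200
held out, reaching held-out R² ≈ 0.95 across seeds; the three-arm ablation
uses 300 samples at 32×32 with a depth-3 network and a 60-epoch budget —
large enough for the masked arms to learn while the whole-image arm is left
leaning on spurious signal; the overfit probe memorizes 8 noiseless images;
bootstrap coverage uses 200 replicates of 60 pairs. The end-to-end smoke
configuration (60 samples, 3 epochs) exercises plumbing, not accuracy.

## Known limitations

* The simulator's causal structure is stipulated, not fitted to any cohort;
  no quantitative color–Hb relation from real patients is embedded.
* Units follow clinical convention (g/dL) over the grid \([5, 20]\);
  sources vary in their unit notation for the same numeric range, and the
  numbers, not the unit string, are what the method uses.
* SMOTE on raw pixels is a blunt instrument; feature-space interpolation is
  available (`smote_balance()` on any feature matrix) and preferable when a
  trained feature extractor exists.
* Single-instance mask metrics deliberately omit confidence-ranked AP; if
  a plugged-in segmenter emits scores, its native COCO-style evaluation
  should be used alongside.
* Training is single-threaded, deterministic, CPU-only; at the full-scale
  configuration (224×224, 300 epochs, n ≈ 1000) a GPU framework is the
  right tool, and this implementation is the desk-scale reference, not a
  production trainer.
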