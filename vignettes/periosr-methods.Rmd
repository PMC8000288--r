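---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(periosr)
```

`periosr` evaluates image resolution-improvement methods in the context of
periodontal bone-loss (PBL) assessment on periapical radiographs, along two
axes: perceived image quality as judged by human observers (visual grading
characteristics analysis of ordinal ratings) and utility for automated
classification (diagnostic metrics from confusion matrices and scored
predictions). This vignette records the models, the parameters that matter,
the numerical conventions, and the design decisions taken where more than
one defensible choice existed.

## Visual grading characteristics (VGC)

Observers rate images on a 4-level mean-opinion-score scale (1 poor,
2 reasonable, 3 good, 4 very high). For a method $M$ and a population of
ratings, the score distribution is $P_M(x) = n_x / n$, and the *top-down*
cumulative is

$$C_M(x) = \sum_{y \ge x} P_M(y), \qquad x = 4, 3, 2, 1,$$

so $C_M(4) \le C_M(3) \le C_M(2) \le C_M(1) = 1$. The VGC curve comparing
methods $A$ (x-axis) and $B$ (y-axis) is the polyline through the anchor
$(0, 0)$ followed by $(C_A(x), C_B(x))$ for $x = 4, 3, 2, 1$; the last
point is always $(1, 1)$. Its trapezoidal area exceeds $1/2$ exactly when
$B$'s ratings stochastically dominate $A$'s, in direct analogy to the ROC
AUC as the two-sample rank statistic.

**Anchor point.** The four $x$-indexed points alone do not close the
polygon at the origin. Prepending $(0,0)$ and applying the trapezoidal rule
reproduces every published group-level AUC of the study this package
re-implements from its raw count blocks, so that construction is adopted
throughout (and self-comparison then gives exactly $1/2$, with the
complement symmetry $\mathrm{AUC}(A,B) = 1 - \mathrm{AUC}(B,A)$).

**Pooling.** Group curves (all experts, all lay observers, everyone) pool
the members' ratings into a single count table. This reproduces the
published expert and lay columns cell for cell. It does *not* reproduce the
published all-observers column (e.g. pooled nearest–bilinear gives 0.601
against a printed 0.544); whatever weighting produced that column is not
stated, so the package reports the pooled-count value and documents the
difference. Two single cells in the published tables differ from the exact
recomputation by one unit in the third decimal (a lay-group AUC of 0.8299
printed as 0.829, and a specificity of 37/52 = 0.7115 printed as 0.711);
the package reports the exact values.

**Wilcoxon tests.** Method pairs are additionally compared with a one-sided
paired Wilcoxon signed-rank test over (observer, image) rating units
(alternative: $B$ rated higher). Zero differences are dropped and tied
absolute differences receive mid-ranks. With $n \le 12$ non-zero
differences the p-value is computed by exhaustive enumeration of all $2^n$
sign assignments conditional on the observed mid-ranks; beyond that, a
normal approximation with the conditional variance $\sum r_i^2 / 4$ (which
absorbs the tie correction) and a 0.5 continuity correction is used. On a
4-level scale ties are ubiquitous, and published p-values additionally
depend on per-image score assignments that aggregate count tables do not
determine — so the test's correctness is established against enumeration,
not against printed p-values.

## Resampling

All resampling is separable (rows, then columns) under the half-pixel-center
mapping $\mathrm{src} = (\mathrm{dst} + 0.5) \cdot (n_\mathrm{in} /
n_\mathrm{out}) - 0.5$, with clamp-to-edge boundary handling and
per-output-pixel normalization of kernel weights. These are the de-facto
conventions of mainstream imaging toolchains; normalization makes every
kernel exactly reproduce constant images and the identity resize. Kernels:
nearest (box, half-width 0.5, round-half-up at the tie, which yields exact
pixel replication at integer factors), triangle (support 1), Keys cubic
with $a = -0.5$ (support 2), and Lanczos-3 ($\mathrm{sinc}(t)\,
\mathrm{sinc}(t/3)$, support 3). Quantization to 8 bits rounds half away
from zero and clips to $[0, 255]$; it is applied only on request or on PNG
export, so intermediate arithmetic stays in double precision.

Downscaling in the evaluation protocol uses an exact box average (each
destination pixel is the area-weighted mean of its source footprint) rather
than any of the kernels under evaluation: the protocol's downscaler is not
stated in the source study, and a neutral choice avoids favoring the
matching upscaler. No anti-alias prefilter is applied to the interpolation
kernels for the same reason. The non-integer 720/128 ratio needs no
cropping under the half-pixel mapping.

## SRCNN

The learned upscaler is the classical three-stage design: bicubic
pre-upscale to the target size, then patch extraction/representation
(9×9 convolution), nonlinear mapping (1×1), and reconstruction (5×5), with
rectification after stages 1–2 and same (zero) padding throughout. The
canonical channel widths are 64/32/1; the package defaults to a 16/8/1
variant, and the test suite uses 8/4/1 — at the phantom scale the network
only needs to learn a mild sharpening residual, and the problem sizes used
for testing (20 training pairs of 32×32 patches, around a hundred
gradient iterations) were chosen so the whole cycle runs comfortably on a
single CPU.

Initialization is near-identity: one channel per stage carries a
center-tap pass-through, remaining weights are $\mathcal{N}(0,
0.001^2)$ perturbations, and biases start at zero — so the untrained
network begins at the bicubic baseline and training learns a residual
correction. Training is full-batch gradient descent on the mean squared
reconstruction error over all pixels, with multiplicative step adaptation:
a step that increases the loss is rejected and the step size halved,
otherwise it grows by 5%. The recorded loss sequence is therefore
non-increasing, and the returned model is the best recorded iterate.
Everything is deterministic given the seed. Internally intensities are
scaled to $[0,1]$; convolutions are evaluated as im2col matrix products,
with the exact adjoint (scatter-add) used for backpropagation — the test
suite verifies the gradients against central differences.

## Image-quality metrics

MSE is the plain per-pixel mean of squared differences; PSNR is
$10 \log_{10}(L^2 / \mathrm{MSE})$ with $L = 255$ fixed (the images are
8-bit), returning `Inf` at zero error. SSIM uses the canonical parameters —
11×11 Gaussian window with $\sigma = 1.5$, $k_1 = 0.01$, $k_2 = 0.03$,
$L = 255$ — and averages the local index over positions where the full
window fits (valid-mode, the original convention). For constant images the
variance terms vanish and SSIM reduces to the closed form
$(2 c_1 c_2 + C_1)/(c_1^2 + c_2^2 + C_1)$, which the tests assert. Note
that per-image PSNR is a deterministic function of per-image MSE, but
aggregate rows (mean over images) are not inter-derivable: the mean of
PSNRs is not the PSNR of the mean MSE. Published aggregate metric rows from
clinical images are therefore not reconstructible from one another and are
not used as reference values; the metric implementations are validated
against closed forms and brute-force references instead.

## Synthetic data

**Phantoms.** `generate_phantom()` builds a stylized periapical-like scene:
bright convex (elliptic) tooth crowns over a darker interproximal corridor,
a brighter alveolar crest band between teeth, and optionally a radiolucent
defect at one interproximal site — *horizontal* (uniform loss of crest
height across the space), *vertical* (a narrow angular defect along one
tooth face, tapering with depth), or *crater* (a semi-elliptic two-walled
trough). Construction is piecewise-constant on five declared intensity
levels, followed by Gaussian blur, additive Gaussian noise, and clipping to
$[0,255]$; the lesion's bounding box is returned as an attribute. The
geometry is deliberately stylized rather than anatomically fitted: the
phantoms exist to give the resampling, quality-metric and rating machinery
controllable structure with known ground truth (piecewise levels, lesion
support, determinism), not to mimic sensor physics, scatter or real
radiographic noise spectra. Consequently, passing tests demonstrate the
correctness of the downstream mathematics, not performance on clinical
radiographs.

**Observer model.** Ratings are simulated from a cumulative-threshold
(ordered-categorical) model: latent $= q_\mathrm{method} +
b_\mathrm{observer} + \varepsilon$, $\varepsilon \sim \mathcal{N}(0,
\sigma^2)$, cut by three increasing thresholds into the four levels. This
is the simplest model that produces the stochastic ordering VGC measures:
raising $q$ shifts every $C(x)$ upward. Defaults: method qualities evenly
spaced by 0.4 along the ordering nearest < bilinear < bicubic < lanczos <
srcnn < srgan (chosen as a moderate effect — adjacent pairs are separated
by well under one noise standard deviation, so single ratings overlap
heavily and only pooling resolves the order), observer biases
$\mathcal{N}(0, 0.3^2)$, noise sd 1, thresholds $(-0.5, 0.5, 1.5)$.
Parameter recovery is verified at 50 observers × 20 images: all 15 ordered
pairs exceed AUC 0.5 in ≥ 95% of replicates.

**Classifier scores.** Class scores are unit-variance Gaussians separated
by $d$, squashed to $[0,1]$ by the logistic function. Squashing is strictly
monotone, so the ROC AUC retains the binormal closed form
$\Phi(d/\sqrt{2})$, which anchors the simulator's calibration tests.

**Seeds.** Every generator is a pure function of its spec including the
seed; pipeline entry points derive per-stage substreams from the run seed
so that stages remain independently reproducible. RNG state of the calling
session is always saved and restored.

## Classifier evaluation

Diagnostic metrics use PBL as the positive class: sensitivity
$\mathrm{TP}/(\mathrm{FN}+\mathrm{TP})$, specificity
$\mathrm{TN}/(\mathrm{FP}+\mathrm{TN})$, precision
$\mathrm{TP}/(\mathrm{FP}+\mathrm{TP})$, NPV
$\mathrm{TN}/(\mathrm{FN}+\mathrm{TN})$, accuracy
$(\mathrm{TP}+\mathrm{TN})/n$. Zero-denominator metrics are reported as an
explicit `NA` plus an `undefined` flag, never as 0. Confusion matrices are
checked against the declared test-set size (104 regions); the bundled
Inception_Bilinear matrix sums to 131 and is flagged rather than silently
accepted — its published metric row is consistent with tp = 47 while the
published accuracy implies tp = 74, so no single correction reconciles it.

ROC curves sweep distinct score thresholds in descending order with ties
grouped (the curve moves diagonally through a tie block), which makes the
trapezoidal AUC equal the rank statistic $P(s^+ > s^-) + \tfrac12 P(s^+ =
s^-)$; the tests verify this against an $O(n^2)$ pairwise oracle. The PR
AUC uses the step convention (precision at each threshold weighted by the
recall increment, as in average precision); the convention is recorded here
because several alternatives exist.

Dataset preparation follows the published protocol with one guard the
protocol leaves implicit: the test quota (52 originals per class) is carved
out before augmentation and never augmented, and the 80:20
train–validation split is made at the original-image level with augmented
copies inheriting their source's side, so no image and its flip can
straddle a boundary. Augmentation is horizontal flip for PBL (doubling)
and horizontal + vertical flips for healthy (tripling); the published
total of 1344 healthy training images is not an integer multiple of any
flip scheme and is therefore not treated as a reference value — the ops
per class are configurable. Histogram equalization maps each level through
the normalized cumulative histogram, $v \mapsto \lfloor 255\,
\mathrm{cdf}(v) + 0.5 \rfloor$, with constant images returned unchanged.

## Problem sizes and determinism

The test suite and the bundled analyses run at desk scale by design:
phantoms up to 96×96 in the protocol examples (the protocol itself is
size-agnostic and defaults to the study's 720→128→720 chain), SRCNN at
8/4/1 channels on 32×32 patches, 100-replicate recovery sweeps, and
10⁴-sample classifier simulations. All stochastic stages take explicit
seeds; protocol reports are byte-identical across repeated runs with the
same seed.

## Known limitations

- Phantoms are geometric caricatures; no claim of radiographic realism.
- The SRGAN method of the source study appears only as a rating label:
  adversarial training is out of scope, so its published image-quality
  table cannot be (and is not) reproduced.
- Published Wilcoxon p-values and the all-observers AUC column are not
  reproducible from the published aggregates (see above); they are covered
  by correctness checks against enumeration and pooled counts instead.
- VGC AUCs are reported without confidence intervals; multi-reader
  multi-case variance modeling is out of scope.
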