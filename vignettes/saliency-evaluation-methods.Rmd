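---
title: "Evaluating CNN saliency against ocular component masks: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating CNN saliency against ocular component masks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the statistic

A CNN that grades diabetic retinopathy outputs a label; whether its
evidence is clinically meaningful is a separate, testable question. The
approach implemented here compares a model's *attention* — its Grad-CAM
map, binarized — with per-component ground-truth masks. For image $X$,
model $f$ and ocular component $c$,

$$\mathrm{IoU}_{X,f,c} =
  \frac{|D_f(X) \cap M_c(X)|}{|D_f(X) \cup M_c(X)|},$$

where $D_f(X)$ is the Otsu-binarized saliency map and $M_c(X)$ the binary
mask of component $c$. Components are the three pathologies
(microaneurysms, hemorrhages, exudates) and three non-pathologies (optic
disc, vessels, and "other": the field of view minus all named
components). Derived summaries: mean IoU per (model, component), pairwise
model agreement (mean IoU between two models' binarized maps, optionally
restricted to one component), and missed pathology (fraction of
4-connected lesion components with insufficient saliency overlap).

## Grad-CAM, precisely

`gradcam()` follows the standard recipe: forward pass; target class
defaults to the *predicted* label; the gradient of the target-class logit
with respect to the last convolutional feature layer is averaged over
space to one weight per channel; the weighted channel sum is rectified,
bilinearly upsampled to image resolution, and min–max normalized to
$[0,1]$. Choices worth stating:

* **Layer.** `model$gradcam_layer` is the final spatial feature node
  (after the last block's activation). At 64-px input this layer is
  16×16, so each cell covers 4×4 image pixels.
* **Normalization.** A well-defined Otsu threshold downstream needs a
  fixed range; a constant map (no spatial preference) maps to all zeros,
  deliberately read as "no attention". Normalization is idempotent.
* **Raw map, not overlay.** Scoring consumes the normalized scalar map;
  RGB overlays are written only for human inspection.

`occlusion_map()` is the gradient-free cross-check: slide a black square
over the image, record the drop in target-class probability, average per
pixel by coverage, clamp negatives, normalize. On models trained with a
known discriminative region, both methods peak in that region and
correlate positively (tested).

## Otsu binarization

The threshold maximizes between-class variance over a 256-bin histogram
(left-open bins on $[0,1]$, the 8-bit convention). Class statistics are
accumulated from the exact pixel values inside each bin, so the selected
cut provably equals an exhaustive search over the 255 candidate
boundaries — the test suite asserts this equivalence, and agreement with
EBImage's independent implementation up to tie-breaking inside empty
histogram gaps. Pixels strictly above the threshold are foreground; ties
go to background; constant maps yield empty foreground.

Undefined scores are first-class: IoU of two empty sets is `NA` and
excluded from every mean (1.0 would reward components absent from an
image, 0.0 would punish correct silence). A (model, component) group with
no defined score reports `NA`, never 0.

## The synthetic scene generator

Real fundus datasets provide labels but not per-pixel causal ground
truth. The generator inverts that: it draws a circular field of view with
a textured warm background, an optic disc, a random-walk vessel tree, and
lesions with known positions — then *derives the grade from the lesion
burden*, so the label's causal signal is known exactly. The grade rule
(monotone in every count; threshold $K=5$ hemorrhages, configurable):
tufts present → 4; hemorrhages $> K$ → 3; any hemorrhage/exudate → 2;
microaneurysms only → 1; else 0. The rule's edge cases (hemorrhages
without microaneurysms; many exudates but few hemorrhages) are resolved
in favour of monotonicity: exudate count alone never reaches grade 3.

Appearance parameters (lesion size ranges, colors, vessel geometry,
noise SD 0.02) were chosen once to make each lesion class visually
distinct at 64–128 px — dark dots (microaneurysms), dark blots
(hemorrhages), bright deposits (exudates) — and are not fitted to any
dataset. Neovascular tufts are drawn as fine vessel tangles and recorded
under the `vessels` mask: the six-component scheme has no tuft class, and
tufts are vessel tissue; their presence is what defines grade 4.

What the generator does **not** emulate: photorealistic texture, camera
optics and illumination artifacts, macular edema, laser scars, image
quality variation. Passing the recovery experiments therefore shows the
*pipeline* is sound — training extracts the causal signal and the scoring
detects it — not that any conclusion transfers to real fundus data. For
real data, `score_only()` consumes user-supplied images, masks and
heatmaps in the documented layout.

## Dataset protocol

`rebalance()` equalizes classes at a cap (default 500 rows per grade):
larger classes are undersampled without replacement, smaller ones
oversampled by repeating rows. `split_manifest()` stratifies 80/10/10 by
grade and keeps all duplicates of one source image in one split — leakage
through oversampling is structurally impossible. `augment()` applies one
random similarity transform to image and masks alike (rotation up to
360°, shifts up to 0.15 of the side, scaling within 0.1, flips);
masks are warped with nearest-neighbour interpolation so they stay
binary; out-of-frame pixels are black and leave every mask.

## Models and training

No deep-learning framework is assumed: the package carries a small
explicit-graph engine (convolution with TF-style "same" padding,
depth-wise convolution, residual add, channel concatenation, global
average pooling, dense head) with hand-written backpropagation, verified
against numerical gradients in the test suite. This is what lets Grad-CAM
read activations and per-logit gradients at any named node. The four
variants share a stride-2 stem and two blocks, differing only in the
block motif, so saliency differences are attributable to architecture
family. Weights use Glorot-uniform initialization; training is Adam
(learning rate 0.001) on categorical cross-entropy, in two phases — head
only (default 5 epochs, convolutions frozen), then the full model
(default up to 100 epochs) with early stopping on validation loss
(patience 20) and best-weight restoration. Training from random
initialization replaces transfer learning at this scale; the two-phase
schedule's semantics are preserved by the freeze.

Desk-scale experiment sizes, chosen to keep a full run in CPU-minutes:
64×64 images, 8 base channels, 50 images per grade, 15 total epochs with
batch size 8. Batch size matters more than it may appear: at 200 training
images, batch 32 yields only ~100 gradient steps, which reliably learns
neither the grade rule nor the watermark control; batch 8 quadruples the
steps and reaches 0.96–1.0 control accuracy within the same 15 epochs.

## The recovery experiment and its control

The central validity check asks: does mean pathology IoU of Grad-CAM maps
exceed what chance placement would give? The null redraws each pathology
mask at a random rotation (about the image center) and translation, with
nearest-neighbour warping, and recomputes the statistic; $p$ is the
fraction of 99 null draws at or above the observed value.

Two details make this null honest:

* **Exchangeability.** Lesions are generated center-biased (within 0.9 of
  the FOV radius). Naively displaced masks pile up against the FOV edge,
  where saliency is systematically rarer — an untrained model "beats"
  such a null. `randomize_mask()` therefore rejects draws that lose more
  than 10% of their pixels to clipping, keeping null placements in the
  same feasible region as real lesions.
* **The control must learn.** The falsification scene encodes the grade
  only in a corner watermark (a bright block whose side grows with the
  grade — area coding, which a global-average-pooled network learns
  reliably) while lesions are drawn independently of the label. The
  falsification logic — pathology IoU consistent with the null, watermark
  IoU far above it — applies only when the model has actually learned the
  watermark; an unconverged model's class gradients are near-random and
  its Grad-CAM tracks generic image structure, lesions included. This is
  why the control's training conditions are sized for convergence.

At these conditions the package reproduces the qualitative published
pattern: non-pathology components (vessels, disc, background) dominate
the saliency maps' IoU over pathology components by a factor of ~3, even
for models whose labels are caused solely by lesions.

## Grading metrics

`overall_metrics()` computes accuracy, Cohen's kappa (marginal-product
chance agreement), the multiclass Matthews correlation ($R_k$ form), and
macro one-vs-rest sensitivity, specificity, PPV, NPV and ROC AUC (via
pROC). The macro one-vs-rest aggregation is a stated choice — consistent
with reporting per-grade SE/SP — since single-number multi-class SE/SP
are otherwise ambiguous; the report records it. One-vs-rest entries for
grades absent from the truth are `NA` and excluded from macro means with
a warning, not imputed. Degenerate cases: kappa of a single-class
confusion matrix is 1 by convention ($p_e = 1$); Matthews is `NA` when a
marginal has zero variance.

## Numerical and interface choices

* Images and masks are 8-bit PNG; heatmaps are stored as 8-bit grayscale
  PNG with a JSON sidecar carrying model id, image id, target class,
  layer and normalization convention. Both the pipeline's scoring stage
  and `score_only()` read heatmaps back from disk, so the two routes are
  byte-identical by construction.
* Image coordinates are row-major, origin top-left; intensities live in
  $[0,1]$.
* Lesion connectivity is 4-connected (EBImage `bwlabel`), stated so
  lesion counts are reproducible; the missed-pathology overlap threshold
  $\tau$ defaults to "any overlap" and a pixel-level missed fraction is
  reported alongside the lesion-level one.
* Every stage derives its RNG stream from the global seed and a stage
  label; reruns with the same config reproduce all CSVs (training-derived
  numbers to within floating-point determinism on one thread).
* Early stopping monitors validation loss (the monitored quantity is
  otherwise unspecified in common practice) and restores best weights.

## Known limitations

* The CNNs are desk-scale analogues, not the published architectures;
  absolute metric values are not comparable to full-scale results — only
  orderings and pass/fail properties are asserted.
* Grad-CAM at a 16×16 feature layer cannot resolve single microaneurysms;
  their IoU is structurally low regardless of model quality.
* The inter-model agreement definition (mean pairwise IoU of binarized
  maps) is one reasonable reading of "mutual agreement in visualization
  space"; Dice or pixel accuracy could be swapped behind the same
  operation.
* The synthetic-to-real gap listed above: conclusions about real fundus
  photographs require real masks via `score_only()`.
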