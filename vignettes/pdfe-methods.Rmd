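---
title: "Patch-based deep feature engineering: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-based deep feature engineering: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Differentiating large vessel occlusion (internal carotid top, MCA-M1; the
thrombectomy-eligible class) from small, distal occlusion (MCA-M3/M4) on
*non-contrast* head CT is hard for humans and valuable to automate, because
many centers that receive stroke patients cannot run CT angiography around
the clock. `pdfe` implements a patch-based transfer-learning pipeline for
this two-class problem: images are resized to a fixed 224-pixel grid, tiled
into 196 non-overlapping 16×16-pixel patches, and a frozen backbone maps the
raw image and every patch to a deep feature vector; the 197 vectors are
concatenated, features are ranked by neighborhood component analysis (NCA),
an iterative selector (INCA) picks the best top-*k* prefix by
cross-validated 1-NN loss, and the selected subset is evaluated with a 1-NN
classifier under stratified tenfold cross-validation.

The pipeline treats patches as independent inputs (an exemplar strategy in
the spirit of a vision transformer's 16×16 tokens), so a localized
abnormality anywhere in the image can contribute features regardless of
position. "16×16" is read as 16×16 *pixels* (hence a 14×14 grid of 196
patches on a 224×224 image); the alternative reading — a 16×16 *grid* of
patches — is rejected but remains reachable through `patch_side`.

## Feature extraction

Two backends satisfy one contract (`output_dim` features per 2-D input,
deterministic, frozen):

* `alexnet_extractor()` builds the canonical AlexNet convolutional
  architecture (five convolutions with ReLU and 3×3/stride-2 max pooling,
  then fc6 and fc7 with 4096 units each) and returns the concatenated
  fc6+fc7 activations, 8192 values per input. Weights are seeded He-normal
  draws by default: the *architecture* — input grid, layer shapes, the
  4096+4096 output contract — is exact, while pretrained ImageNet weights
  can be supplied through the `weights` argument when available. Inputs are
  bilinearly resized to the 227-pixel input side (the canonical AlexNet
  grid; the pipeline's 224 grid is the patching geometry, not the backbone
  geometry), replicated to three channels, and normalized with the ImageNet
  channel statistics. Activations are taken post-ReLU, the common
  transfer-learning convention; `activation = "pre"` switches.
* `fallback_extractor()` applies a seeded random linear projection
  (Gaussian entries, variance 1/d_in) to the flattened input resized to a
  32-pixel side, followed by rectification — a training-free random-features
  map with the same contract and default width. It is the recommended
  backend for fully reproducible CPU-only runs and is what the package's
  own end-to-end experiments use.

Fusion is plain concatenation in a *fixed documented order* (raw image
first, patches row-major; fc6 before fc7 within an input), because feature
indices must be reproducible for the selection stage and for provenance
queries (`feature_provenance()`). With defaults the fused width is
(1+196)×8192 = 1,613,824 columns.

## NCA weighting

The weighting stage maximizes, by gradient ascent from the all-ones vector,

$$\xi(w) = \sum_i p_i \;-\; \lambda \sum_r w_r^2, \qquad
p_i = \sum_{j \ne i,\, y_j = y_i} p_{ij}, \qquad
p_{ij} = \frac{\exp(-d_w(x_i, x_j)/\sigma)}{\sum_{l \ne i} \exp(-d_w(x_i, x_l)/\sigma)},$$

with the weighted-L1 distance
$d_w(x_i,x_j) = \sum_r w_r^2\,|x_{ir} - x_{jr}|$. Tunable parameters
(`nca_config()`):

* `sigma` (default `"auto"`): kernel width. **Auto resolves to the mean
  pairwise distance at the initial weights.** A fixed width of 1 is
  degenerate at realistic widths: with ~1.6M standardized columns the
  initial distances are of order 10^6, every `exp(-d)` underflows, and after
  max-shifted normalization the reference distribution collapses onto the
  single nearest neighbor, where the gradient is exactly zero and the
  ascent cannot move. Scaling σ to the distance magnitude keeps the softmax
  in its informative regime at any width; σ may still be fixed numerically.
* `lambda_reg` (default 1/n): the ℓ2 penalty that drives uninformative
  weights toward zero; 1/n keeps the penalty commensurate with the
  objective's O(n) data term.
* `learning_rate` (default 0.01) with backtracking: a step is halved until
  the objective does not decrease, so *accepted steps are monotone* by
  construction, and grows mildly (×1.2) after acceptance.
* `max_iters` (default 100) and `tol` (default 1e-6, relative objective
  improvement). The **pipeline** default caps at 30 accepted iterations: the
  selector consumes only the weight *ranking*, which stabilizes within tens
  of iterations at the fused width, long before the objective converges.
* `standardize` (default on): columns are centered/scaled first;
  zero-variance columns are mapped to exactly zero, contribute nothing to
  any distance, and keep only their shrunk initial weight.

The objective depends on weights only through their squares, so the sign is
irrelevant; final weights are reported as magnitudes (hence nonnegative).
The analytic gradient is verified against central finite differences in the
test suite. The pairwise scans are blocked over contiguous column ranges in
compiled code, so memory traffic is one pass over the matrix per evaluation
regardless of width; blocked and unblocked results are identical.

## INCA selection

Features are sorted by weight (descending; ties toward the lower column
index), and each prefix size `k` in the loop range (default 1–500) is scored
by the stratified `loss_folds`-fold (default 10) cross-validated
misclassification of a 1-NN Euclidean classifier on the top-`k` columns.
Two details matter for comparability and determinism:

* the folds are drawn **once** per call and reused for every `k` — loss
  differences across `k` then reflect the features, not fold noise;
* within the loss, standardization is fitted on the training folds only,
  and squared distances are accumulated incrementally column-by-column in
  ranked order, which is algebraically identical to recomputing each prefix
  from scratch (the suite checks exact equality against a brute-force
  oracle).

`chosen_k` is the loss minimizer with the smallest-`k` tie-break. The
selected count is dataset-specific — on its own phantoms the package
typically selects a few dozen features.

## Final evaluation

The 1-NN classifier uses plain Euclidean distance and no distance
weighting ("voting: none" — vacuous at k = 1), with deterministic
tie-breaks: equal distances go to the lower training index; split votes (an
even `k`) go to the nearest neighbor's label. Metrics are computed from the
**pooled** tenfold confusion matrix — accuracy, recall, precision, F1, in
percent — with the large-occlusion class (label 0) as positive; undefined
ratios are reported as `NA` with a warning, never silently as zero. A
`average = "macro"` flag averages both class orientations instead. The
nine-classifier benchmark (`benchmark_classifiers()`) runs kNN, decision
tree, random forest, linear/quadratic discriminant, logistic regression,
naive Bayes, SVM and MLP under *identical* fold assignments, the comparison
classifiers in their engines' standard defaults (recorded in each report);
a fit that fails on given data (e.g. a singular covariance for QDA when a
class has fewer samples than features) yields an `NA` report rather than an
aborted benchmark.

## Selection scope and leakage

In the classical protocol the selector sees the complete dataset and the
selected subset is then cross-validated (`selection_scope = "full"`).
Because `chosen_k` minimizes a CV loss computed on the same samples, and the
ranking itself used every label, this estimate is *optimistically biased* —
with tens of samples and ~10^5–10^6 candidate features, features that
separate any labeling by chance are abundant, and the bias can be severe.
`selection_scope = "nested"` repeats NCA and INCA inside every training
fold and classifies the held-out fold with that fold's own subset, at
`folds` times the selection cost; this is the configuration the package's
null-control test uses (phantoms with effect size 0 must score at chance
level), and the honest way to estimate generalization. The headline
surrogate experiment intentionally uses the full protocol — it mirrors the
classical pipeline — but on strongly separated classes, where the signal,
not the bias, drives the result.

## The synthetic phantom

Real stroke CT datasets are rarely shareable, so the package ships a seeded
generator (`synth_config()`, `generate_image()`, `generate_dataset()`)
whose phantoms have exactly the statistical structure the pipeline assumes:
a dark background, a bright elliptical "skull" rim, mid-gray "brain"
parenchyma (ellipse with semi-axes 0.36/0.44 of the image side), and one
disk of elevated intensity — the occlusion analogue — at a seeded uniform
location strictly inside the brain, plus i.i.d. Gaussian pixel noise,
clipped (not rescaled) to [0, 1] so intensity semantics stay stable.

* The **class difference is the lesion radius** (defaults 28 px vs 8 px on
  a 256-px image), matching the large/small-occlusion semantics, with
  shared contrast.
* The **lesion location varies per image**, so the discriminating signal is
  position-invariant and patch-level features matter; nothing can key on a
  fixed pixel.
* The signal amplitude is `effect_size × lesion_contrast` (defaults 1 ×
  0.15); `effect_size = 0` makes the classes identically distributed *by
  construction*, giving an exact null. Contrast 0.15 and noise 0.05 were
  chosen once as a plausible soft-tissue-window regime: a clearly visible
  but noisy lesion at effect size 1, unmistakable at 2.
* Images are written as 8-bit grayscale PNG; the 8-bit quantization is part
  of the contract (real CT exports are ≥8-bit rasters), and the whole
  dataset is a pure function of the configuration (per-image seeds derive
  from `seed` and the image index).

What the phantom does *not* emulate: anatomy (no ventricles, no
hemispheric texture, no partial-volume effects), Hounsfield-unit physics,
windowing variation, or inter-scanner differences. Passing tests on
phantoms therefore demonstrate that the pipeline's machinery — geometry,
feature plumbing, weighting, selection, evaluation — behaves as specified
and can exploit a localized size/contrast signal; they say nothing about
clinical performance on real CT.

## Numerical choices and degenerate inputs

* PNG/TIFF intensities are scaled by the decoder's native bit depth (code
  255 → 1.0); no min–max renormalization, so constant images stay constant
  and are flagged with a warning rather than zeroed. RGB inputs reduce by
  Rec. 709 luminance. DICOM is not read directly; export slices to
  PNG/TIFF first.
* Bilinear interpolation everywhere (resizing is the identity when the
  size already matches); interpolated values are clipped back to [0, 1].
* All tie-breaks (weight ranking, distance, vote, `chosen_k`) are fixed and
  documented, so every stage is a pure function of its inputs and seeds;
  reruns are bitwise identical.
* Compiled pairwise scans use 4096-column blocks with four independent
  accumulators; results do not depend on the block size.

## Problem sizes in the shipped experiments

The package's own experiments are sized for a single CPU: the headline
surrogate uses 40 images per class (effect size 2, fallback extractor at
the full 8192-per-input width, loop 1–500, tenfold CV); the null control
uses 20 per class at effect 0 with a 256-wide fallback under nested
selection; the effect-size monotonicity check uses 30 per class at a width
of 128 across effect sizes {0, 0.5, 2}; planted-feature recovery uses 100
samples × 100 features over 20 seeded replicates. These sizes are the
package's choices for its reference experiments, not limits of the
implementation — the stages stream and block, so wider matrices and larger
cohorts scale linearly in time.

## Known limitations

* The random-weight AlexNet backbone is architecture-faithful but
  untrained; with pretrained weights the *features* change (and typically
  improve), while every structural contract tested here is unchanged.
* `chosen_k` and the loss curve are dataset-specific; numbers from one
  cohort (including the phantom experiments) do not transfer.
* At very wide feature spaces with little or no signal, even nested
  estimates are noisy, and selection-driven pipelines can score *below*
  chance on null data for particular draws; the null-control test bounds
  the estimate within a 99% binomial band around chance rather than
  expecting 50% exactly.
* The two-class design is deliberate; there is no multi-class support, and
  no ROC/AUC (the four reported metrics are the pipeline's contract).
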