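# pdfe — patch-based deep feature engineering for two-class brain-CT screening

`pdfe` implements a patch-based deep feature engineering pipeline for
two-class grayscale image classification. The motivating application is
screening non-contrast head CT for **large vessel occlusion** (top of the
internal carotid artery, MCA-M1) versus **small vessel occlusion**
(MCA-M3/M4 distal branches): the large-occlusion class is the
thrombectomy-eligible one, so a fast image-only triage signal is clinically
valuable at centers without around-the-clock CT angiography. The package is
aimed at researchers who want a fully reproducible, testable implementation
of this pipeline — including a seeded synthetic phantom generator, since
clinical CT datasets are rarely shareable.

## The method

For each grayscale image `I` (intensities in [0, 1]):

1. **Resize** to the network grid, `224 × 224` (bilinear).
2. **Tile** into non-overlapping `16 × 16` pixel patches, row-major:
   `P_0 … P_195` (a `14 × 14` grid).
3. **Extract deep features** from the raw image and every patch with a
   frozen backbone. With the AlexNet-architecture backbone the feature of an
   input `x` is `f(x) = [fc6(x), fc7(x)] ∈ R^8192` (4096 + 4096 activations
   of the sixth and seventh fully connected layers).
4. **Fuse** by concatenation in fixed order (raw first, then patches
   row-major): `F(I) = [f(I), f(P_0), …, f(P_195)]`, giving
   `(1 + 196) × 8192 = 1,613,824` features per image.
5. **Weight** features by neighborhood component analysis (NCA): maximize
   the regularized expected leave-one-out same-class neighbor mass
   `ξ(w) = Σ_i p_i − λ Σ_r w_r²` under the weighted-L1 distance
   `d_w(x_i, x_j) = Σ_r w_r² |x_ir − x_jr|` and softmax reference
   probabilities `p_ij ∝ exp(−d_w(x_i, x_j)/σ)`.
6. **Select** with the iterative selector (INCA): rank features by weight,
   then for every `k` in the loop range `1…500` score the top-`k` prefix by
   stratified tenfold cross-validated 1-NN misclassification; keep the best
   `k` (ties to the smallest).
7. **Classify** with 1-NN (Euclidean, no distance weighting) under
   stratified tenfold cross-validation; report accuracy, recall, precision
   and F1 (percent) from the pooled confusion matrix, with the
   large-occlusion class as positive. A nine-classifier benchmark harness
   (kNN, DT, RF, LD, QD, LR, NB, SVM, MLP) runs under identical folds.

Two extractor backends satisfy one contract: `alexnet_extractor()` (the
exact AlexNet architecture; seeded random He-initialized weights by default,
pretrained weights loadable via its `weights` argument) and
`fallback_extractor()` (a seeded random linear projection of the resized
input followed by rectification) — deterministic, training-free, and the
recommended backend for reproducible CPU-only experiments.

Because the selected subset is chosen on the full dataset in the classical
protocol (`selection_scope = "full"`), the cross-validated estimate of the
selected features is optimistically biased; `selection_scope = "nested"`
re-runs weighting and selection inside every training fold for an unbiased
estimate. See the methods vignette (`vignettes/pdfe-methods.Rmd`).

## Worked example

```r
library(pdfe)

# 1. a small synthetic two-class dataset (large vs small lesions)
cfg <- synth_config(n_class0 = 15, n_class1 = 15, effect_size = 2, seed = 42)
ds  <- generate_dataset(cfg)

# 2. fused patch + raw deep features (seeded random-projection extractor)
ex <- fallback_extractor(seed = 42, output_dim = 512)
fm <- build_feature_matrix(ex, ds$records)
dim(fm$values)
#> [1]     30 100864

# 3. NCA weighting and the INCA top-k loop
w   <- nca_weights(fm, config = nca_config(max_iters = 30))
sel <- inca_select(fm, weights = w, k_max = 500, loss_folds = 10, seed = 42)
sel$chosen_k
#> [1] 5
min(sel$losses)
#> [1] 0

# 4. final 1-NN evaluation on the selected features
rep <- cross_validate("kNN", fm$values[, sel$selected_indices], fm$labels,
                      folds = 10, seed = 42)
rep
#> <evaluation_report> kNN (10-fold CV, seed 42)
#>   confusion: TP=15 TN=15 FP=0 FN=0
#>   accuracy 100.00%  recall 100.00%  precision 100.00%  f1 100.00%
```

The fused matrix has `(1 + 196) × 512` columns; the selector keeps 5 of
them with zero tenfold 1-NN loss, and the final pooled confusion is perfect
on these strongly separated phantoms (30 images, effect size 2). `run_pipeline()`
wraps steps 2–4 (plus artifact serialization) behind one
`pipeline_config()`; `inst/cli/pdfe.R` exposes the same stages as shell
subcommands (`synth`, `extract`, `select`, `classify`, `benchmark`, `run`).

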