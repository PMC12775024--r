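# fawfusion

Multimodal RGB–thermal image fusion for detecting fall armyworm
(*Spodoptera frugiperda*, FAW) infestation in maize leaves.

Visible and thermal images of an infested leaf carry complementary signals:
RGB shows dark chewed feeding lesions, thermal shows locally elevated
emission — and either cue can be missing in any one pair (occlusion,
washed-out thermal contrast). `fawfusion` implements a binary classifier
(label **0 = FAW**, **1 = Healthy**) along two fusion paths and an ablation
harness that quantifies what fusion buys:

- **Feature-level fusion** — per-modality CNN extractors (two 3×3
  convolutions, channels 64 → 128, each with ReLU and 2×2 max-pooling, then
  a fully connected map to a 256-vector), concatenation
  `F_fused = [F_rgb, F_thermal]` (length 512, RGB block first), and a
  512 → 1024 → 512 → 2 fully connected classifier with dropout 0.5, trained
  end to end with cross-entropy and Adam.
- **Image-level fusion** — the two preprocessed images stacked into a
  6-channel input `I_fused = [I_RGB, I_thermal]`, classified by a vision
  transformer whose 16×16/stride-16 convolutional patch embedding is
  widened to 6 channels, trained with AdamW.

Around the models: aspect-preserving preprocessing
(`scale_factor = target_size / max(w, h)`, truncating resize onto a padded
224×224 canvas, channelwise normalization), evaluation (confusion-matrix
metrics, ROC/AUC via a threshold sweep whose trapezoidal area equals the
Mann–Whitney statistic, PR curves, stratified K-fold), PCA feature-space
visualization, and a seed-deterministic **synthetic paired-image
generator** with ground-truth lesion/hotspot masks, so the whole pipeline
is testable offline. The neural-network layers (convolutions, pooling,
attention, backpropagation, Adam/AdamW) are implemented in the package,
with the hot path in single-precision RcppArmadillo kernels.

## Worked example

The whole pipeline — simulate a 200-pair dataset, preprocess at 96×96,
train three arms on the shared 80/20 split, evaluate on the held-out 40
pairs — runs with one call; a single seed fans out deterministically to
the data, the split, and the per-arm training seeds:

```r
library(fawfusion)

rep <- run_ablation(run_config(seed = 12,
                               arms = c("rgb_only", "thermal_only",
                                        "fused_feature")))
print(rep)
#> Ablation study (seed 12 - 160 train / 40 test)
#>            arm accuracy precision recall    f1   auc
#>       rgb_only    0.900     1.000    0.8 0.889 0.925
#>   thermal_only    0.825     0.933    0.7 0.800 0.815
#>  fused_feature    0.925     0.947    0.9 0.923 0.975
```

(About 7 minutes on one CPU.) Accuracy is the held-out fraction correct;
precision/recall/F1 refer to the positive FAW class (label 0), and AUC uses
the softmax probability of FAW as the score. The fused arm beats both
unimodal arms because the generator deliberately splits the class signal
across modalities: with a 25% chance each that the RGB or the thermal cue
is suppressed, a single modality tops out near 0.875 while the fused model
can approach 0.97.

The pieces compose individually too:

```r
ds <- generate_dataset(generator_config(n_pairs = 60, seed = 11), "demo")
split <- split_train_test(ds$samples$label, 0.8, seed = 11, stratified = TRUE)
prep <- preprocess_dataset(ds$samples, preprocess_config(target_size = 96),
                           train_idx = split$train)
pair <- prep$pairs[[1]]
dim(fuse_images(pair))              # 6-channel stacked image: 6 96 96
model <- rep$models$fused_feature
f <- fuse_features(extract_features(model, pair, "rgb"),
                   extract_features(model, pair, "thermal"))
length(f)                           # 512, RGB block first
classify_fused(model, f)$label      # 0 = FAW, 1 = Healthy
```

A command-line front end covering the same operations ships at
`inst/cli/fawfusion` (`simulate`, `train`, `evaluate`, `ablate`,
`visualize`).

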