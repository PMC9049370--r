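# stainseg

Carcinoma vs. non-carcinoma recognition of H&E-stained breast
histopathology images, built around a **two-stage nuclei segmentation
strategy**, in pure R.

Hematoxylin stains nuclei blue-purple; eosin stains cytoplasm and stroma
pink. The distribution, size and density of nuclei carry most of the
signal separating carcinoma from non-carcinoma tissue, so the pipeline
first isolates the nuclear stain, then segments nuclei, then classifies:

1. **Stain separation.** The optical density `V = log(I0 / I)` of an RGB
   image is factorized by sparse non-negative matrix factorization,

   `min 1/2 ||V − WH||_F² + λ Σ_j ||H(j,·)||₁`, `W, H ≥ 0`, `||W(:,j)||₂ = 1`,

   with λ = 0.2, giving the stain color matrix `W` (3×2) and density maps
   `H`. The hematoxylin channel rendered alone is the *foreground* image.
2. **Nuclei segmentation.** Frequency-tuned saliency (CIELab distance to
   the blurred image) gates foreground markers obtained by
   morphological-reconstruction filtering; background markers are the
   ridge lines of the distance-transform watershed of the Otsu nuclei
   mask; a marker-controlled watershed then floods the Sobel gradient.
3. **Features.** Completed local binary patterns (CLBP, P = 8, R = 1;
   59-bin uniform histograms of the sign and magnitude codes → 118 dims)
   on the nuclei image, fused with a 64-color × {1,3}-distance
   auto-correlogram (128 dims) of the foreground → 246 dims.
4. **Classification.** RBF-kernel SVM (c = 2, g = 1) on min-max scaled
   patch features; each image gets 20 random 512×512 patches and is
   called non-carcinoma iff strictly more than 10 patches vote
   non-carcinoma.
5. **Evaluation.** Accuracy / sensitivity / specificity / precision / F1
   (carcinoma positive), ROC/AUC, and Dice / Hausdorff for segmentation.

A Beer–Lambert synthetic H&E generator (`make_scene`, `make_dataset`)
provides images with exact stain matrices, nuclei masks and class
structure, so every stage is testable without external datasets.

## Worked example

```r
library(stainseg)

# a synthetic H&E scene with known ground truth
gt  <- make_scene(scene_spec(image_size = c(256, 256), n_nuclei = 12,
                             seed = 42))
img <- render_rgb(gt)

# stain separation: recovered stain vectors vs. truth
fit <- estimate_stains(rgb_to_od(img), seed = 1)
abs(colSums(fit$model$W * gt$W_true$W))
#> [1] 0.9997 0.9998            # cosine similarity per stain column

# two-stage segmentation
seg <- segment_nuclei(img, stain_cfg = list(seed = 1))
max(seg$labels)                 # 12 nuclei found (12 placed)
dice((seg$labels > 0) * 1L, gt$mask)
#> [1] 0.929

# fused patch feature
length(patch_features(seg$nuclei, seg$foreground))
#> [1] 246

# metrics from a confusion table
print(classification_metrics(list(TP = 15, FN = 3, TN = 18, FP = 0)))
#> Accuracy 91.67% | Sensitivity 83.33% | Specificity 100.00% | Precision 100.00% | F1 90.91%
```

`run_pipeline()` chains everything (segmentation → patch features → SVM
→ vote → metrics) over a dataset from `make_dataset()` or an on-disk
manifest; `inst/cli/stainseg.R` exposes `synth`, `separate`, `segment`
and `run-all` subcommands for shell use.

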