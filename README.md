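# earcount

Counting wheat ears in nadir field photographs taken at the grain-filling
stage — when ears have yellowed against still-green stems and leaves — for
plant phenotypers and breeders who need per-image ear counts without manual
annotation.

## The method

The pipeline is *classify-then-sum*. An image is contrast-enhanced in
CIELAB (CLAHE on L, clip limit 2, 8 × 8 tiles, then a 3 × 3 median filter),
colour-quantized by K-means with *k* = 3 into soil, leaf/stem, and ear
clusters, and the ear cluster (largest b\*) is binarized and cleaned by a
6 × 6 morphological opening and a 3 × 3 closing. Each 8-connected blob is
cropped (bounding box + margin), resized to 100 × 100, and classified by a
five-conv-layer CNN into one of four classes — non-ear, 1, 2, or 3 ears —
so ears that touch and segment as a single blob ("adhesion") are still
counted correctly, and bright non-ear blobs are absorbed by class 0. The
image count is the sum of the labels.

Classification is scored with per-class precision *P*ᵢ = TPᵢ/(TPᵢ+FPᵢ),
recall *R*ᵢ = TPᵢ/(TPᵢ+FNᵢ), F1ᵢ = 2*P*ᵢ*R*ᵢ/(*P*ᵢ+*R*ᵢ), and their
macro (unweighted mean) and micro (pooled TP/FP/FN) averages. Counting is
scored against manual counts *m*ᵢ with predictions *c*ᵢ by

    R²    = 1 − Σ(mᵢ − cᵢ)² / Σ(mᵢ − m̄)²
    RMSE  = sqrt( Σ(mᵢ − cᵢ)² / n )            [ears]
    RRMSE = RMSE / m̄ × 100                     [%]
    bias  = Σ(mᵢ − cᵢ) / n                      [ears]

Because no field imagery is deposited with the method, the package includes
a synthetic canopy-scene generator with exact ground truth (soil, leaf
clutter, speckled elliptical ears, controlled adhesion) so the whole stack
is testable end to end.

## Worked example

```r
library(earcount)

# a synthetic scene: 10 ears, 30% of them fused into multi-ear blobs
sc <- generate_scene(scene_config(size = c(300, 300), n_ears = 10,
                                  adhesion = 0.3, seed = 42))
sc
#> <scene 300 x 300: 10 ears in 8 blob(s)>

seg <- segment_image(enhance(sc$image), seg_config(seed = 1))
seg
#> <segmentation: 8 candidate region(s), ear cluster 1>
head(seg$regions, 3)
#> # A tibble: 3 × 9
#>   region_id row_min col_min height width centroid_row centroid_col  area
#>       <int>   <int>   <int>  <int> <int>        <dbl>        <dbl> <int>
#> 1         1      48     228     26    38         60.4         246.   487
#> 2         2      55      95     46    42         74.6         116.  1331
#> 3         3     104     186     30    25        119.          198.   343
```

Every one of the 10 ears lies in one of the 8 blobs — two blobs are fused
pairs/triples, which is exactly what the classifier handles. Train a small
model on synthetic patches and count the scene:

```r
ps <- generate_patch_dataset(150, scene_config(seed = 7))
ds <- balance_and_split(ps, per_class = 150, test_per_class = 30,
                        augmentation_config(seed = 8))
model <- build_model(cnn_config(preset = "desk"), seed = 9)
model <- train_cnn(model, ds, train_config(steps = 400, batch_size = 32,
                                           learning_rate = 1e-3, seed = 10))

evaluate_classifier(model, ds$test)
#> <confusion_matrix>
#>          predicted
#> true      class_0 class_1 class_2 class_3
#>   class_0      30       0       0       0
#>   class_1       0      30       0       0
#>   class_2       0       1      27       2
#>   class_3       0       0       5      25

count_image(sc$image, model, seg_config(seed = 1),
            preprocess_config(crop = NULL, scale = NULL), image_id = "demo")
#> # A tibble: 1 × 8
#>   image_id region_count tally_0 tally_1 tally_2 tally_3 predicted_count
#> 1 demo                8       0       7       0       1              10
```

The count table reads: 8 candidate regions, 7 classified as single ears and
1 as a three-ear blob, so the predicted count is 7 + 3 = 10 — the true
number. The residual classifier confusions sit in the 2-vs-3-ear classes,
which is where errors concentrate for this family of methods. At the
package's full desk scale (600 patches/class, 1200 training steps) held-out
patch accuracy is typically 96–98% and count R² over 30 scenes of 5–40 ears
is above 0.95; see the vignette for the protocol.

There is also a command-line interface (`inst/cli/earcount.R`) with
subcommands `enhance`, `segment`, `synth`, `build-dataset`, `train`,
`count`, and `evaluate`, driven by a YAML config and a single global seed.

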