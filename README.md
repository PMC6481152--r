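# mcseg

Two-stage convolutional detection and segmentation of breast
microcalcifications (MCs) in grayscale mammogram-like images, with a
synthetic phantom generator so the whole pipeline can be trained, run and
evaluated end to end without clinical data.

Microcalcifications are sub-millimetre calcium deposits that appear as
small, locally bright blobs; clusters of them can be an early sign of
breast cancer. The package is aimed at researchers in medical image
analysis who want a compact, fully inspectable reference implementation of
the patch-based two-CNN approach:

1. **Detector** — screens `N x N` image tiles (default `N = 49`, overlapped
   by `floor(N/2) = 24` px per axis; background tiles are skipped via Otsu
   thresholding) for the presence of an MC anywhere in the tile.
2. **Segmentator** — classifies every foreground pixel inside a flagged
   tile from the `N x N` patch centred on it, producing a binary MC mask.
3. **Cluster analysis** — connected components of the mask become MC
   objects; a sliding 1 cm² window flags cluster regions wherever strictly
   more than 5 distinct MC centroids fall inside (the radiological density
   rule; 200 px at the default 0.05 mm/pixel spacing).

Both CNNs share one architecture: six 3x3 stride-1 convolutions (max-pool
2x2 after the first two), FC-64 and FC-2 heads, ReLU + batch normalization,
50% dropout, He initialization. Class posteriors are softmax
`p(y = l | X) = exp(s_l) / sum_k exp(s_k)`; training minimizes the
categorical cross-entropy `H(y, p) = -sum_j y_j log p_j` with Adam on
balanced 256-patch minibatches (equal positives and negatives, random
dihedral augmentation), halving the `1e-3` learning rate on validation-loss
plateaus, with early stopping. Patches are labelled by the four-class
taxonomy C1 (centre pixel is MC), C2 (MC within 3 px of the centre), C3
(MC only peripheral), C4 (no MC); C1–C3 are detector-positive, C1 alone is
segmentator-positive. The conv/BN/dropout/Adam engine is implemented in
the package with RcppArmadillo and is verified against finite-difference
gradients in the test suite.

## Worked example

Generate a phantom with one spatial cluster of nine MCs, label the mask,
and apply the density rule:

```r
library(mcseg)

cfg <- phantom_config(n_clusters = 1, n_mcs = 9, cluster_radius_px = 70, seed = 7)
ph  <- generate_phantom(cfg)
ph
#> <mc_phantom> 256 x 256 px @ 0.05 mm/px, 366 MC pixels in 9 lesion(s)

objs <- label_components(ph$mask)
head(objs, 3)
#> # A tibble: 3 × 8
#>      id n_pixels centroid_row centroid_col row_min row_max col_min col_max
#>   <int>    <int>        <dbl>        <dbl>   <int>   <int>   <int>   <int>
#> 1     1       41         165           92      162     168      89      95
#> 2     2       56         205.         106.     201     209     102     110
#> 3     3       38         116.         110.     112     119     107     113

detect_clusters(objs, dim(ph$mask), ph$pixel_spacing_mm, exact = TRUE)
#> <cluster_report> 9 MC object(s); 1 cluster region(s) (window 200 px = 10 mm, > 5 MCs)
```

The nine lesions were injected within 70 px of one centre, i.e. inside a
single square centimetre, so exactly one cluster region is reported, with
all nine centroids inside (`mc_count = 9`). With `n_clusters = 0` the MCs
scatter over the whole breast and no window exceeds five centroids.

A complete experiment — phantom dataset, patch database, training of both
networks, whole-image evaluation — is one call:

```r
study <- run_phantom_study(seed = 1)
study$evaluation$lesion_recall   # fraction of true lesions touched by the mask
study$evaluation$pixel           # pooled pixel confusion, accuracy, FPR
tidy(study$segmentator)          # training history (loss/accuracy per step)
autoplot(study$segmentator)      # training curves
```

On held-out phantoms the default study finds essentially every lesion
(lesionwise recall 0.9–1.0 across seeds) with whole-image pixel
false-positive rates of roughly 0.4–1.2%, concentrated on the ambiguous
soft-contour shells of the lesions; the methods vignette
(`vignettes/microcalcification-pipeline.Rmd`) analyses this envelope and
how pixel FPR couples to lesion density.

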