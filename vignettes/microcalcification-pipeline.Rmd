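---
title: "Two-stage convolutional detection and segmentation of microcalcifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage convolutional detection and segmentation of microcalcifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

Microcalcifications (MCs) are sub-millimetre calcium deposits that appear in
mammograms as small, locally bright blobs; clusters of them can be an early
sign of breast cancer. Finding them automatically is hard for classical
image processing because breast tissue is highly heterogeneous: no global
intensity threshold or fixed morphological filter separates a faint MC from
bright connective tissue.

`mcseg` implements a two-stage, patch-based convolutional approach:

1. a **detector** CNN screens overlapped `N x N` tiles of the image
   (default `N = 49`, tiles overlapped by `floor(N/2) = 24` px per axis) and
   flags tiles that appear to contain an MC anywhere;
2. a **segmentator** CNN then classifies *every foreground pixel inside a
   flagged tile* from the `N x N` patch centred on it — positive when the
   centre pixel belongs to an MC — producing a binary lesion mask.

The two stages trade compute for sensitivity: the detector touches each
pixel a handful of times, while the expensive per-pixel segmentation runs
only inside candidate regions. Background pixels are excluded up front by
Otsu thresholding of the intensity histogram. The predicted mask is finally
decomposed into connected components (8-connectivity), and cluster regions
are reported wherever a sliding 1 cm² window contains **strictly more than
5** distinct MC centroids, the radiological density rule.

Both networks share one architecture: six 3x3 stride-1 convolutions (2x2
max-pooling after the first and second), two fully connected layers of 64
and 2 units, ReLU activations, batch normalization after every layer except
the last, 50% dropout on the FC-64 layer, and He initialization. Class
scores are mapped to posteriors with a softmax,
$p(y = l \mid X) = e^{s_l} / \sum_k e^{s_k}$, and training minimizes the
categorical cross-entropy $H(y, \hat{y}) = -\sum_j y_j \log \hat{y}_j$ by
Adam on balanced minibatches of 256 patches, with an initial learning rate
of $10^{-3}$ halved whenever the validation loss plateaus, and early
stopping returning the weights of the best validation loss.

With *valid* (unpadded) convolutions the spatial side shrinks by 2 per
layer; for a 49x49 patch the sequence is 49 → 47 → 23 → 21 → 10 → 8 → 6 → 4
→ 2, so 2x2 feature maps enter the fully connected head. *Same* (zero-
padded) convolutions preserve the side (49 → 24 → 12 after the two pools).
`feature_map_side()` implements this arithmetic and rejects geometries that
underflow (e.g. a 29-px patch on the valid path).

## The synthetic phantom generator

Clinical mammograms with pixel-level MC annotations are rarely shareable,
so the package ships a phantom generator that makes every downstream stage
testable with pixel-exact ground truth:

- **Breast region**: a half-ellipse against the left image edge with a
  logistic-smoothed tissue-to-background transition and a gentle intensity
  gradient toward the chest wall. The transition zone is a few pixels wide —
  enough to exercise the well-known failure mode of patch classifiers at
  strong contrast edges.
- **Tissue texture**: Gaussian-smoothed white noise (correlation length
  `tissue_texture_scale`, amplitude 0.06 on the `[0, 1]` intensity scale),
  standing in for the variability of connective, glandular and adipose
  tissue without modelling anatomy.
- **Microcalcifications**: thresholded anisotropic Gaussian bumps. Each blob
  has a diameter drawn from `mc_diameter_range` (default 3–12 px = 0.15–0.6
  mm at the default 0.05 mm/pixel), a peak contrast drawn from
  `mc_contrast_range` (default 0.25–0.75 of the local background
  intensity), a random orientation and axis ratio, and a contour warped by
  low-order angular harmonics scaled by `mc_shape_irregularity`. The mask is
  exactly the set of pixels whose warped radial coordinate is below the
  contour threshold; the intensity bump extends beyond it as a sub-threshold
  shoulder, so contours are soft and boundary pixels are genuinely
  ambiguous — the synthetic analogue of the partial-volume effect.
- **Noise**: optional additive white noise (`noise_sigma`), which can be
  raised to mimic the widespread noise of digitized film.

Placement is rejection sampling with a separation rule guaranteeing that
distinct blobs never touch (so the mask has exactly `n_mcs` 8-connected
components), optionally grouped around cluster centres within
`cluster_radius_px`. Everything is driven by a single seed: the same
configuration reproduces the same phantom bit for bit.

```{r phantom}
library(mcseg)
ph <- generate_phantom(phantom_config(seed = 42))
ph
autoplot(ph)
```

What the phantoms deliberately do **not** model: projective anatomy
(vessels, ducts, pectoral muscle), arterial "tram-track" calcifications,
scanner-specific noise spectra, and BIRADS-relevant morphology. Passing the
end-to-end tests therefore demonstrates that the pipeline's mechanics and
optimization work, not that the trained weights transfer to clinical
images.

## The patch taxonomy and the database

Every Otsu-foreground pixel is an eligible patch centre (windows crossing
the border are completed by reflect padding). Classes follow the position
of MC pixels relative to the centre:

| class | definition | detector label | segmentator label |
|-------|------------|----------------|-------------------|
| C1 | centre pixel is MC | positive | positive |
| C2 | centre is background, nearest MC pixel within 3 px (Euclidean) | positive | negative |
| C3 | MC in the window, but farther than 3 px from the centre | positive | negative |
| C4 | no MC anywhere in the window | negative | negative |

The C2 radius is configurable (`c2_radius_px`); the shell at distance 1–2
px is folded into C2 so the four classes partition all windows.
`build_patch_index()` computes classes for all centres at once with exact
Euclidean-disc and box dilations of the reflect-padded mask, and the test
suite verifies the result against per-window `classify_patch()` calls.

Records (coordinates + class, never pixels) can be persisted to a SQLite
file. Minibatches are assembled on the fly: exactly half positive and half
negative for the requested network, drawn uniformly from the records of
each label, each patch receiving one of the eight dihedral symmetries
(four right-angle rotations × optional flip — the centre pixel is fixed, so
the class is invariant). Draws are independent across batches, so two
minibatches virtually never coincide, which adds useful randomness to the
batch-norm statistics.

## Numerical choices

- Pooling uses floor division on odd sides (validated by the 49 → 2
  valid-path arithmetic; ceiling would give 3x3).
- Batch normalization follows the activation of each convolution and of the
  FC-64 layer; normalization is over batch × spatial positions per channel,
  `eps = 1e-5`; inference uses running statistics (exponential moving
  average, momentum 0.1).
- Dropout is inverted (mask scaled by `1/(1-p)` at train time), so
  inference needs no rescaling.
- The softmax subtracts the per-sample maximum before exponentiation; the
  cross-entropy clamps the log argument at `1e-12` (user-facing
  `crossentropy()`); training uses an internal clamp at the smallest
  representable double.
- The decision rule is the posterior argmax with ties broken toward
  negative: a pixel or tile is positive only when its positive posterior
  strictly exceeds 0.5. The threshold is exposed for ROC exploration.
- The engine computes heavy tensors in single precision (parameters and
  results cross to R as doubles); gradients were verified against finite
  differences, and an all-double variant of the same backward pass agreed
  with finite differences to ~1e-10 relative during development.
- Degenerate inputs fail loudly: constant images cannot be Otsu-split,
  even-sided windows are rejected, non-finite training losses abort with a
  divergence diagnostic, and impossible blob placements raise a
  placement-failure error after bounded retries.
- Per-image intensities are z-scored (whole-image mean and standard
  deviation) before either network, identically at training and inference.

Two open conventions are resolved as follows and exposed as arguments:
"balanced" validation/test pools can be balanced per label or per class —
the evaluation module reports both; and a flagged tile's pixels outside the
Otsu foreground are *not* segmented, consistent with excluding background
from all further evaluation.

## The phantom study and its performance envelope

`run_phantom_study()` runs the full experiment: 30 phantoms of 192x192 px
with 8 MCs each (16 train / 4 validation / 10 test, split at image level),
a patch pool capped at 250 records per image (5,000 across the 20
training+validation phantoms; caps 60/40/40/110 for C1–C4, weighting the
negative pool toward plain tissue as in a natural index), both networks
with filters 8-8-24-24-48-48 on the valid path, 256-sized minibatches, 250
(detector) and up to 650 (segmentator) Adam steps. One study runs in about
five minutes on a single CPU core; all sizes are package choices made to
keep a complete, repeatable experiment cheap, and they are far below a
clinical-scale training run.

```{r study}
study <- run_phantom_study(seed = 1)
study$evaluation$pixel          # pooled pixel metrics, both domains
study$evaluation$lesion_recall  # fraction of lesions touched
tidy(study$segmentator)         # training history
study$patch_tables$segmentator  # per-class error rates, both balance rules
```

Across seeds, the study lands in a stable envelope: lesionwise recall
0.9–1.0 — essentially every injected MC is found — and all-pixels
false-positive rates of roughly 0.4–1.2%, with per-class patch errors of a
few percent for C1, C3 and C4 and 20–30% for C2. Two structural facts
explain the FPR level, and both are worth understanding before comparing
against clinical-scale numbers:

1. **Errors concentrate on boundary pixels.** C2 patches — centre within 3
   px of an MC but outside it — sit exactly on the soft, partial-volume-like
   shoulder of each blob, where the ground-truth contour is a convention
   more than a visible edge. This is the hardest class for the segmentator
   by an order of magnitude, consistent with it being the hardest class in
   clinical evaluations of the same architecture.
2. **Pixel FPR couples to lesion density.** The ≤3 px shell around true MCs
   occupies about 1.6% of a study phantom (8 lesions in 192² px). Even a
   15% C2 error — the level a clinical-scale training of the valid-path
   architecture reaches — implies ~0.25% whole-image FPR from boundary
   disagreement alone before any tissue false positive. Clinical mammograms
   are thousands of pixels on a side with a comparable lesion count, so the
   same per-class errors yield whole-image FPRs orders of magnitude
   smaller. Whole-image pixel rates are therefore only comparable between
   images of similar lesion density, which is why `pixel_metrics()` reports
   the full confusion counts alongside the rates, and why
   `lesionwise_recall()` — insensitive to boundary pixels — is the better
   headline for small phantoms.

## Known limitations

- The phantom breast outline is fixed (only texture, noise and lesions are
  randomized); the generator makes no claim of anatomical realism.
- The detector and segmentator must share the patch side `N`.
- The per-pixel segmentation is patch-by-patch by design; a fully
  convolutional reformulation would be far faster but is out of scope.
- Cluster detection counts component centroids: a component spanning a
  window border counts for the window containing its centroid.
- Training is single-threaded CPU; the engine is sized for phantom studies,
  not clinical-scale corpora.
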