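---
title: "phenoscreen: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenoscreen: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

phenoscreen scores protein-localization phenotypes in high-content
fluorescence microscopy screens, entirely on a local machine. A screen images
thousands of fields of transfected cells in three channels — a nucleus stain,
a transfection reporter, and the tagged target protein — and the scientific
question is how the target protein's subcellular distribution (nuclear,
nuclear-excluded, or diffuse) shifts across genetic variants. The per-variant
fraction of cells with nuclear localization serves as a proxy for loss of
function, to be correlated against an orthogonal functional assay.

The pipeline has four analysis stages — image quality control, cell
detection, unsupervised phenotype discovery, supervised phenotype scoring —
plus a synthetic-field generator that provides full ground truth so that
every stage is testable without any real data or download. This vignette
records the models behind each stage, the parameters that matter, and the
choices made where the design was genuinely open.

## Image quality control

Automated microscopes defocus occasionally and do not discriminate against
fields with air bubbles, fibers, or grossly overexposed cells. The focus
statistic is the **variance of the Laplacian**: the image is convolved with
the 4-neighbour kernel

```
 0  1  0
 1 -4  1
 0  1  0
```

over the valid (border-free) region and the *population* variance of the
response is returned. In-focus images are edge-rich and score high.
The 4-neighbour kernel and valid-region convolution are our choices — the
operator family is standard but the exact kernel and border handling are
not canonical; excluding the border keeps the statistic free of padding
artifacts. Population (not sample) moments are used everywhere in the
package, following image-processing convention.

Two aberrations defeat the raw statistic, and each gets a suppression step
before the measure is taken:

* **Air bubbles / fibers** produce thin bright rings and streaks with strong
  gradients. Grayscale dilation (square structuring element, side 5,
  2 iterations) collapses thin bright structures into plateaus with little
  interior gradient while only thickening genuine cell content.
* **Overexposed cells** have saturated plateaus with razor-sharp rims.
  Pixels at or above 98% of the saturation value are masked, the mask is
  dilated by 7 px, and the masked region is replaced by a Gaussian-blurred
  (sigma 15) copy, leaving every unmasked pixel untouched. The 0.98 / 7 px /
  sigma 15 values were fixed once so that a synthetic saturated blob
  demonstrably lowers the focus measure after suppression.

The QC decision threshold is **calibrated** on a labeled set by exhaustively
scanning the observed measures as candidate cuts and keeping the one that
maximizes accuracy, breaking ties toward the larger (stricter) threshold.
Confusion-matrix metrics use the *retained-in-focus* orientation: a true
positive is an in-focus field that was kept, a true negative a blurry field
that was removed. The default focus channel is the nucleus stain because it
is present in every cell, transfected or not; it is configurable.

SNR throughout the package is the common convention: mean pixel value
divided by the population standard deviation of pixel values. A constant
image reports `Inf` with a warning.

## Cell detection

Detection places bounding boxes around transfected cells; it is not
segmentation (the screens use sub-confluent cultures, so boxes suffice).
The package defines a detector *contract* — field in, ranked scored boxes
out — with a classical reference implementation: Otsu threshold on the
pixel-wise max of the reporter and target channels, connected components
filtered to [60, 6000] px, rejection of components whose reporter support
is below 30% of their area (this excludes nucleus-only distractor cells),
bounds padded by 15% and clipped, and a score that squashes the component's
mean contrast over background into [0, 1]. The contract makes the trainable
backend pluggable; the reference detector is deterministic and
download-free.

Evaluation is PASCAL-style: predictions are matched greedily in descending
score order (ties broken by larger IoU), each truth box used at most once,
a prediction counting as a true positive iff its best available IoU reaches
the threshold (default 0.5). **Average precision** is the all-points
interpolated area under the precision–recall curve: at each recall level
the precision envelope is the maximum precision at that recall or higher.

Training augmentation is a fixed registry of **14 transforms** (identity,
rot90/180/270, horizontal/vertical flip, rot90+flip, brightness ±0.15,
contrast ×1.3/×0.7, inversion, Gaussian noise at sigma 0.02 and 0.05).
Identity is counted among the 14, so a 141-image training set becomes
exactly 1,974 images. Geometric transforms map normalized boxes exactly;
photometric ones leave them bit-identical.

The **noise-robustness sweep** corrupts each evaluation field with seeded
additive Gaussian noise at multiplier m of a step sigma (default 0.13 in
[0, 1] intensity units), re-runs detection, and records precision, recall,
AP and the mean target-channel SNR. The step was chosen once so the default
multipliers {1, 2, 3} span the full regime from mild degradation to
catastrophic recall collapse on the standard fixture, with the mean SNR
crossing 1.5 between multipliers 1 and 2 — the same qualitative picture that
motivates the "keep SNR above 1.5" guidance for real screens.

## Phenotype discovery

Discovery is unsupervised: detected cells are cropped, embedded, cleaned of
a noise cluster, subclustered, and summarized by exemplars that a human
labels.

**Feature extraction.** The default extractor is the first four
convolutional blocks of the VGG-16 architecture (3×3 convolutions + ReLU,
2×2 max-pools; 64-64 / 128-128 / 256×3 / 512×3 channels), implemented here
as a pure-R forward pass (im2col + BLAS matrix products). ROIs are scaled
to 148×148 on input. Standard VGG-16 arithmetic gives a 9×9×512 block-4
output at that size (41,472 values), not the 8,192-length feature map this
pipeline standardizes on; we therefore adaptive-average-pool the block-4
output to a 4×4 grid over its 512 channels, which yields 8,192 exactly and
is recorded in the extractor fingerprint. A 64×64 input mode, which
produces the 4×4×512 grid natively, is also provided. Weights are seeded
random (He initialization) by default so the whole package runs offline
and deterministically; random convolutional features act as a fixed
nonlinear projection and preserve class structure well enough for the
synthetic benchmarks. `weights_source = "pretrained"` loads a user-supplied
RDS weight file for transfer-learning-quality features. A classical,
weight-free **radial-profile extractor** (32 radial mean-intensity bins of
the target channel about the nucleus centroid, plus the in-nucleus target
fraction and mean intensity) is provided as a fast alternative; it is
purpose-built for nuclear/nuclear-excluded/diffuse patterns and is the
extractor the end-to-end benchmarks use.

**Reduction.** Features are PCA-reduced to at most 500 components, then
UMAP embeds them to 30 dimensions for clustering and, in a separate run
with identical hyperparameters, to 2 dimensions for visualization. UMAP
runs with n_neighbors = 100 (clamped to n−1 with a warning), min_dist =
0.1, and the **Chebyshev** metric. The installed UMAP backend (`uwot`) has
no Chebyshev option, so the package computes the exact Chebyshev
k-nearest-neighbor graph itself (`stats::dist(method = "maximum")`) and
passes it to the optimizer as precomputed neighbors — the stated metric is
honored exactly rather than approximated. Runs are single-threaded and
seeded, making the embedding reproducible. Clustering always operates on
the 30-dimensional coordinates; the 2-D embedding is visualization only.

**Noise removal.** The embedding is split into 2 groups by spectral
clustering; the smaller group is the noise candidate. It is discarded
automatically only when it holds under 20% of the ROIs — real noise
clusters are small (a few percent), and a 40/60 "noise" split more likely
reflects genuine structure, so anything larger is retained with a warning
and exemplar montages for manual review.

**Subclustering and model selection.** Spectral clustering uses a
symmetrized kNN affinity graph (10 neighbors, locally scaled Gaussian
weights), the symmetric normalized Laplacian, and seeded k-means on the
row-normalized bottom eigenvectors; labels are remapped to descending
cluster size for stability. The subcluster count is chosen by sweeping k
and maximizing the **mean silhouette coefficient**
s = (b − a) / max(a, b), with singleton clusters scoring 0 and Euclidean
distance on the 30-dim coordinates (Chebyshev is used only inside UMAP);
ties go to the smaller k. Per cluster, the 20 nearest retained points to
the centroid (mean of the 30-dim coordinates) are exported as labeled
exemplar montages — the human-in-the-loop step that names the phenotype
classes.

## Phenotype scoring

The reference classifier is a linear discriminative pipeline on the
discovery features: standardize, project onto at most 64 principal
components, fit multinomial logistic regression. The split is stratified
80/20, seeded; training refuses fewer than 2 classes and warns below 100
examples per class (the recommended floor). The backend is pluggable, and
classification refuses features whose extractor fingerprint differs from
the model's. Ties in predicted probability break toward the alphabetically
first class. Training ROIs should be harvested through the same
detect-and-crop path as the cells to be scored; training on idealized
centered sprites and scoring field crops shifts the input distribution and
degrades accuracy (the package's tests train through the real path).

Each variant's score is the empirical distribution of its cells' predicted
classes; the **nuclear fraction** is the headline scalar, following the
hypothesis that nuclear accumulation of a normally nuclear-excluded protein
indicates loss of function. Variant scores are inner-joined (exact,
case-sensitive ids; mismatches reported, never silently dropped) with an
external LOF table, and the association is summarized by the sample Pearson
correlation with a two-sided p-value from the exact t transform
t = r·sqrt(n−2)/sqrt(1−r²) on n−2 degrees of freedom, plus an OLS best-fit
line for the scatter plot. The t transform with two-sided reference is our
choice of convention; at r = 0.759 with 13 variants it gives p ≈ 0.003.

## The synthetic generator

The generator emulates what the pipeline needs to see, not photorealism:

* sub-confluent fields of elliptical cells (radius 14–22 px, random
  orientation and eccentricity 0.7–1) whose nuclei never overlap and whose
  bodies are nearly disjoint (centers at least 0.95× the summed radii
  apart);
* three channels composed on flat backgrounds (nucleus 0.25, reporter 0.22,
  target 0.22 on the [0, 1] scale) with smooth sigmoid cell edges
  (softness 1.2 px);
* **intracellular speckle texture** — smoothed multiplicative granularity
  (nucleus amplitude 0.45, correlation ~1.5 px) emulating chromatin and
  vesicular structure. This is the high-frequency content that defocus
  destroys; without it, smooth synthetic cells give a focus statistic that
  any realistic noise floor swamps, and focus QC has nothing to measure.
  Texture and amplitudes are scaled so sprite peaks stay below saturation:
  overexposure occurs only as an explicit artifact, never as a texture
  accident;
* 70% of cells transfected (reporter + target), 30% nucleus-only
  distractors that detection must ignore;
* the three localization phenotypes with per-cell intensity jitter: the
  nuclear pattern concentrates target signal inside ~80% of the nucleus
  ellipse, the nuclear-excluded (wildtype-like) pattern fills the cytosol
  with an exclusion zone 1.25× the nucleus, the diffuse pattern fills the
  whole cell;
* degradation applied after ground truth is frozen: optional artifacts
  (bubble ring, fiber streak, saturated blob with recorded masks), Gaussian
  defocus blur, and additive Gaussian noise at sigma
  `base_noise_sigma × noise_multiplier`, clipped to [0, 1]. The default is
  mild acquisition noise (base 0.08 × multiplier 0.25 = sigma 0.02);
  robustness experiments add whole multiples on top.

Every random draw derives from one spec seed through a stable integer hash
(placement, sprites, artifacts and noise use separate streams), so a field
is bit-reproducible and changing, say, the blur setting does not perturb
the noise draw. Datasets are written as multi-page 16-bit TIFFs (page order
nucleus, reporter, target — recorded in the manifest) with normalized-
coordinate annotation CSVs.

What the generator does **not** emulate: optical point-spread functions,
structured background autofluorescence, illumination gradients, confluent
or touching cells, and multi-well plate layout. Passing the synthetic
benchmarks therefore demonstrates that the algorithms are implemented
correctly and behave sensibly across focus, noise, and phenotype-mixture
regimes — it does not certify performance on real micrographs, where
channel bleed-through, debris and staining variability add failure modes
this generator never produces.

## Benchmark scales and determinism

The package validates itself at desk scale: 141 source images for the
augmentation arithmetic; 40 calibration + 100 test fields (512 px) for the
QC benchmark; 20 clean fields for detection AP; 12 fields × multipliers
{0, 1, 2, 3} for the noise sweep; planted feature blobs with k ∈ {2, …, 5}
for cluster-count recovery; and an end-to-end study of 8 variants × 150
cells (256 px fields, radial extractor) in which the planted monotone
LOF–nuclear-fraction relationship is recovered with r > 0.9. These sizes
were chosen to exercise each contract well inside a desktop CPU budget.

Determinism rules: all stochastic steps take explicit seeds; stage seeds
fan out from one global seed via a stable hash; UMAP runs single-threaded;
re-running a pipeline with the same config produces hash-identical stage
outputs, which the run manifest records (MD5 per output file, plus every
threshold, seed, and discarded-item count).

## Known limitations

* The random-weights extractor is a fixed random projection, not a learned
  representation; on real data, pretrained weights (supplied as an RDS
  file) or the radial profile should be preferred.
* The reference detector assumes bright cells on a darker, roughly uniform
  background; it will fragment under heavy noise (by design — that is the
  regime the sweep documents) and merge touching cells.
* Threshold calibration places the cut at the weakest in-focus calibration
  measure; with small calibration sets, borderline sharp fields near that
  measure can be removed. Larger calibration sets tighten this.
* Silhouette-based model selection assumes compact, separated clusters;
  overlapping phenotype continua will bias the chosen k downward.
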