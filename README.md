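# phenoscreen

Local, cloud-free phenotype scoring for high-content fluorescence
microscopy screens.

High-content screens image thousands of fields of transfected cells in
three channels — nucleus stain, transfection reporter, tagged target
protein — to ask how a protein's subcellular localization shifts across
genetic variants. For proteins that are normally excluded from the nucleus,
the per-variant fraction of cells with *nuclear* localization is a useful
proxy for loss of function (LOF), and can be correlated against orthogonal
functional assays to help classify variants of uncertain significance.
phenoscreen implements the full analysis path for such screens, for
bench scientists and image-analysis engineers who want every stage
reproducible on one machine:

1. **Image quality control** — variance-of-Laplacian focus measures
   (4-neighbour kernel, valid-region convolution, population variance),
   with grayscale dilation to suppress air-bubble/fiber edges and
   mask-and-blur suppression of overexposed cells; threshold calibration
   by exhaustive accuracy scan. Metrics use the retained-in-focus
   orientation (a true positive is an in-focus field that was kept).
2. **Cell detection** — a deterministic reference detector (Otsu threshold
   on max(reporter, target), connected components, area and
   reporter-support filters, padded boxes, contrast scores) behind a
   pluggable detector contract; PASCAL-style greedy matching; all-points
   interpolated average precision (A.P.); a 14-transform training
   augmentation registry (141 images → exactly 1,974); and a seeded
   noise-robustness sweep reporting precision/recall/A.P. against the mean
   image SNR (SNR = mean pixel / population SD of pixels).
3. **Phenotype discovery** — per-ROI feature maps (VGG-16 convolutional
   blocks 1–4 with adaptive average pooling to 8,192 features, seeded
   random or user-supplied pretrained weights; or a fast radial-profile
   extractor), PCA to ≤500 components, UMAP to 30 dimensions
   (n_neighbors = 100, min_dist = 0.1, exact Chebyshev neighbor graph),
   removal of a small noise cluster, silhouette-guided spectral
   subclustering (s = (b−a)/max(a,b), ties to smaller k), and 20
   nearest-centroid exemplars per cluster for human labeling.
4. **Phenotype scoring** — a linear classifier (standardize → PCA →
   multinomial logistic regression) over the discovery features with a
   stratified held-out split; per-variant class distributions and nuclear
   fractions; Pearson correlation of nuclear fraction against an LOF
   table with the exact two-sided t-transform p-value
   (t = r√(n−2)/√(1−r²), df = n−2) and an OLS best-fit line.

A **synthetic field generator** with complete ground truth (boxes,
phenotype labels, focus labels, artifact masks) makes all of the above
testable end to end without any download; it is first-class, tested code.

## Worked example

```r
library(phenoscreen)

## 1. a labeled synthetic study: 12 fields, three channels, full ground truth
spec <- synthetic_spec(image_size = 256, cells_per_field = c(6, 9),
                       transfected_fraction = 0.8, seed = 42)
fields <- lapply(1:12, function(i) {
  s <- spec; s$seed <- derive_seed(42, paste0("field", i))
  generate_field(s, id = sprintf("field_%02d", i))
})

## 2. focus QC: blur half the fields, calibrate a threshold, filter
blurry <- lapply(fields[7:12], function(g) {
  s <- spec; s$seed <- derive_seed(42, g$field$id); s$blur_sigma <- 5
  generate_field(s, id = paste0(g$field$id, "_blur"))
})
all_fields <- c(lapply(fields[1:6], `[[`, "field"), lapply(blurry, `[[`, "field"))
thr <- calibrate_threshold(all_fields, rep(c("in_focus", "blurry"), each = 6))
qc <- qc_batch(all_fields, list(threshold = as.numeric(thr)))
cat(sprintf("QC kept %d of %d fields (threshold %.2e)\n",
            length(qc$kept), length(all_fields), as.numeric(thr)))

## 3. detect cells in the kept fields and evaluate against ground truth
kept_truths <- lapply(fields[1:6], function(g) g$truth$boxes)
dets <- lapply(qc$kept, detect_cells)
print(evaluate_detections(dets, kept_truths))

## 4. correlate per-variant nuclear fractions with an external LOF table
lof <- data.frame(variant = c("WT", "G129E", "R173H"),
                  lof_score = c(0.05, 0.78, 0.35))
labels <- list(WT    = c(rep("nuclear", 2), rep("nuclear_excluded", 14), rep("diffuse", 4)),
               G129E = c(rep("nuclear", 13), rep("nuclear_excluded", 3), rep("diffuse", 4)),
               R173H = c(rep("nuclear", 7), rep("nuclear_excluded", 8), rep("diffuse", 5)))
scores <- do.call(rbind, Map(score_variant, names(labels), labels))
print(correlate_lof(scores, lof))
```

prints

```
QC kept 6 of 12 fields (threshold 6.37e-04)
<detection_metrics> precision=1.000 recall=1.000 AP=1.000 (IoU>=0.50, 37 truths, 37 preds)
<correlation_result> r = 0.999, p = 0.03184, n = 3 (LOF = -0.095 + 1.331 x nuclear_fraction)
```

The QC step removed exactly the six defocused fields; the detector found
all 37 annotated transfected cells (and none of the nucleus-only
distractors) with perfect average precision on this clean set; and the
three variants' nuclear fractions (0.10, 0.65, 0.35) track the supplied
LOF scores almost perfectly — r close to 1, with the n = 3 p-value from
the exact t transform. In a real screen the per-cell labels in step 4 come
from `classify_rois()` with a model trained on exemplar-labeled ROIs (see
`train_classifier()`), and `run_pipeline()` drives all stages from one
config file. A command-line front end is installed at
`system.file("scripts", "phenoscreen", package = "phenoscreen")` with
`generate`, `qc`, `detect`, `augment`, `eval-detect`, `noise-sweep`,
`discover`, `score` and `run` subcommands.

## Package layout

* `R/synthetic.R` — field/sprite generator, artifacts, TIFF + CSV datasets
* `R/qc.R` — focus measures, suppression, calibration, SNR, batch QC
* `R/detection.R`, `R/augment.R` — detector, matching, PR/A.P., transforms
* `R/features.R` — ROI cropping, conv-net and radial extractors, montages
* `R/discovery.R` — PCA + UMAP reduction, spectral clustering, silhouette,
  noise split, exemplars
* `R/scoring.R` — classifier, variant scores, correlation analytics
* `R/pipeline.R` — config, stage orchestration, run manifest
* `vignettes/phenoscreen-methods.Rmd` — models, parameters, design choices
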