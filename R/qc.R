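# Image quality control: variance-of-Laplacian focus measures with artifact
# suppression, SNR estimation and controlled noise injection.
#
# Orientation convention throughout: the POSITIVE class is an in-focus image
# that is retained; blurry images that are removed are true negatives.

#' Variance-of-Laplacian focus measure
#'
#' Convolves the image with the 4-neighbour 3x3 Laplacian kernel
#' `[[0,1,0],[1,-4,1],[0,1,0]]` over the valid (border-free) region and
#' returns the population variance of the response. In-focus images are
#' edge-rich and score high; defocused images score low.
#'
#' @param image numeric matrix (single channel), at least 3 x 3.
#' @return non-negative scalar focus measure.
#' @export
laplacian_variance <- function(image) {
  stopifnot(is.matrix(image), is.numeric(image))
  nr <- nrow(image); nc <- ncol(image)
  if (nr < 3 || nc < 3) {
    stop_phenoscreen("image must be at least 3x3 for the Laplacian kernel (got ",
                     nr, "x", nc, ")")
  }
  ri <- 2:(nr - 1); ci <- 2:(nc - 1)
  lap <- image[ri - 1, ci] + image[ri + 1, ci] +
         image[ri, ci - 1] + image[ri, ci + 1] - 4 * image[ri, ci]
  pop_var(lap)
}

#' Suppress air-bubble edges by grayscale dilation
#'
#' Grayscale morphological dilation with a square structuring element
#' thickens bright plateaus and collapses the thin bright rings of air
#' bubbles into blobs with little interior gradient, removing their spurious
#' contribution to the focus measure.
#'
#' @param image numeric matrix on [0,1].
#' @param size structuring-element side (odd), default 5.
#' @param iterations number of dilation passes, default 2.
#' @return dilated image (same dimensions).
#' @export
suppress_bubbles <- function(image, size = 5L, iterations = 2L) {
  stopifnot(is.matrix(image), size >= 1, iterations >= 0)
  if (size %% 2 == 0) size <- size + 1L
  kern <- EBImage::makeBrush(size, shape = "box")
  out <- EBImage::Image(image)
  for (i in seq_len(iterations)) out <- EBImage::dilate(out, kern)
  eb_mat(out)
}

#' Suppress overexposed (saturated) regions
#'
#' Masks pixels at or above `saturation_fraction` of the saturation value,
#' dilates the mask, and replaces the masked region with a Gaussian-blurred
#' copy of the image, removing the sharp rims of saturated cells while
#' leaving every unmasked pixel untouched.
#'
#' @param image numeric matrix on [0,1]; saturation value 1.
#' @param saturation_fraction mask threshold as a fraction of saturation
#'   (default 0.98).
#' @param mask_dilation mask dilation radius in pixels (default 7).
#' @param blur_sigma sigma of the in-fill Gaussian blur (default 15).
#' @return image with saturated regions blurred in place.
#' @export
suppress_overexposed <- function(image, saturation_fraction = 0.98,
                                 mask_dilation = 7L, blur_sigma = 15) {
  stopifnot(is.matrix(image))
  mask <- image >= saturation_fraction
  if (!any(mask)) return(image)
  brush <- EBImage::makeBrush(2L * as.integer(mask_dilation) + 1L, shape = "disc")
  mask <- eb_mat(EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0.5
  blurred <- ebimage_blur(image, blur_sigma)
  out <- image
  out[mask] <- blurred[mask]
  out
}

#' Focus-score one field
#'
#' Runs the QC chain on the configured focus channel: artifact suppression
#' (bubble dilation, then overexposure masking+blur, order configurable)
#' followed by the variance-of-Laplacian focus measure. Reports the raw
#' (unsuppressed) measure alongside, and decides keep/remove against the
#' threshold.
#'
#' @param field a `field_image`.
#' @param config list; recognized entries `channel` (default `"nucleus"`),
#'   `threshold` (numeric; `NA` leaves `keep` as `NA`), `suppress_order`
#'   (default `c("bubbles", "overexposed")`), plus the suppression defaults
#'   `bubble_size`, `bubble_iterations`, `saturation_fraction`,
#'   `mask_dilation`, `blur_sigma`.
#' @return one-row data frame of class `focus_report`: `image, raw_variance,
#'   focus_measure, threshold, keep, bubbles_suppressed,
#'   overexposure_suppressed`.
#' @export
focus_score <- function(field, config = list()) {
  cfg <- utils::modifyList(list(channel = "nucleus", threshold = NA_real_,
                                suppress_order = c("bubbles", "overexposed"),
                                bubble_size = 5L, bubble_iterations = 2L,
                                saturation_fraction = 0.98, mask_dilation = 7L,
                                blur_sigma = 15), config)
  chan <- field_channel(field, cfg$channel)
  raw <- laplacian_variance(chan)
  img <- chan
  did <- c(bubbles = FALSE, overexposed = FALSE)
  for (step in cfg$suppress_order) {
    if (step == "bubbles") {
      nxt <- suppress_bubbles(img, cfg$bubble_size, cfg$bubble_iterations)
      did["bubbles"] <- !identical(nxt, img)
      img <- nxt
    } else if (step == "overexposed") {
      nxt <- suppress_overexposed(img, cfg$saturation_fraction,
                                  cfg$mask_dilation, cfg$blur_sigma)
      did["overexposed"] <- !identical(nxt, img)
      img <- nxt
    } else {
      stop_phenoscreen("unknown suppression step '", step, "'")
    }
  }
  fm <- laplacian_variance(img)
  keep <- if (is.na(cfg$threshold)) NA else fm >= cfg$threshold
  structure(data.frame(image = field$id, raw_variance = raw,
                       focus_measure = fm, threshold = cfg$threshold,
                       keep = keep,
                       bubbles_suppressed = did[["bubbles"]],
                       overexposure_suppressed = did[["overexposed"]],
                       stringsAsFactors = FALSE),
            class = c("focus_report", "data.frame"))
}

#' Calibrate the focus threshold on labeled fields
#'
#' Exhaustively scans candidate cuts (the observed focus measures, plus one
#' above the maximum) and returns the threshold maximizing accuracy in the
#' retained-in-focus orientation (`keep` iff measure >= threshold). Ties are
#' broken toward the larger (stricter) threshold.
#'
#' @param fields list of `field_image`s, or a numeric vector of
#'   pre-computed focus measures.
#' @param focus_labels character vector, `"in_focus"` / `"blurry"`, one per
#'   field.
#' @param config passed to [focus_score()] when `fields` are images.
#' @return the calibrated threshold (numeric scalar), with attributes
#'   `accuracy` (achieved on the calibration set) and `measures`.
#' @export
calibrate_threshold <- function(fields, focus_labels, config = list()) {
  labs <- as.character(focus_labels)
  if (length(unique(labs)) < 2L) {
    stop_phenoscreen("calibration needs both in-focus and blurry fields")
  }
  measures <- if (is.numeric(fields)) {
    fields
  } else {
    vapply(fields, function(f) focus_score(f, config)$focus_measure, numeric(1))
  }
  stopifnot(length(measures) == length(labs))
  pos <- labs == "in_focus"
  cands <- sort(unique(c(measures, max(measures) + 1)))
  acc <- vapply(cands, function(t) mean((measures >= t) == pos), numeric(1))
  best <- max(acc)
  thr <- max(cands[acc >= best - 1e-12])   # stricter tie-break
  if (best <= 0.5 + 1e-12) {
    warning("calibrated threshold separates classes poorly (accuracy ",
            signif(best, 3), ")")
  }
  structure(thr, accuracy = best, measures = measures)
}

#' Confusion-matrix QC metrics
#'
#' Counts use the retained-in-focus orientation: true positives are in-focus
#' fields kept, true negatives blurry fields removed, false positives blurry
#' fields kept, false negatives in-focus fields removed.
#'
#' @param keep logical keep decisions.
#' @param focus_labels ground-truth labels, `"in_focus"` / `"blurry"`.
#' @return list of class `qc_metrics`: `tp, fp, tn, fn, accuracy, precision,
#'   recall`.
#' @export
qc_metrics <- function(keep, focus_labels) {
  if (length(keep) == 0) stop_phenoscreen("qc_metrics: empty input")
  stopifnot(length(keep) == length(focus_labels))
  pos <- focus_labels == "in_focus"
  tp <- sum(keep & pos); fp <- sum(keep & !pos)
  tn <- sum(!keep & !pos); fn <- sum(!keep & pos)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
                 recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_),
            class = "qc_metrics")
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat(sprintf("<qc_metrics> tp=%d fp=%d tn=%d fn=%d | accuracy=%.3f precision=%.3f recall=%.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$accuracy, x$precision, x$recall))
  invisible(x)
}

#' Signal-to-noise ratio of an image
#'
#' The common image-processing convention: mean pixel value divided by the
#' population standard deviation of pixel values. A constant image has no
#' measurable noise; its SNR is reported as `Inf` with a warning.
#'
#' @param image numeric matrix or array.
#' @return list of class `snr_stats`: `mean_pixel`, `std_pixel`, `snr`.
#' @export
compute_snr <- function(image) {
  x <- as.numeric(image)
  if (length(x) == 0) stop_phenoscreen("compute_snr: empty image")
  m <- mean(x); s <- pop_sd(x)
  if (s == 0) {
    warning("constant image: SNR reported as Inf")
    snr <- Inf
  } else {
    snr <- m / s
  }
  structure(list(mean_pixel = m, std_pixel = s, snr = snr), class = "snr_stats")
}

#' Add controlled Gaussian noise to an image
#'
#' Adds i.i.d. Gaussian noise with sigma `multiplier * base_sigma`, clipped
#' to [0,1]. Deterministic given `seed`; `multiplier = 0` returns the input
#' bit-identically.
#'
#' @param image numeric matrix or array on [0,1].
#' @param multiplier unitless noise multiplier, >= 0.
#' @param base_sigma base noise sigma in intensity units (default 0.08, the
#'   generator's standard level).
#' @param seed integer seed.
#' @return noisy image, same dimensions.
#' @export
add_gaussian_noise <- function(image, multiplier, base_sigma = 0.08, seed = 1L) {
  if (multiplier < 0) stop_phenoscreen("noise multiplier must be >= 0")
  if (multiplier == 0 || base_sigma == 0) return(image)
  noise <- with_seed(seed, stats::rnorm(length(image), 0, multiplier * base_sigma))
  out <- image + array(noise, dim(image) %||% length(image))
  clip01(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Batch quality control
#'
#' Applies [focus_score()] to every field, returns the kept subset (input
#' order preserved) and the per-field report table; optionally writes the
#' report CSV.
#'
#' @param fields list of `field_image`s.
#' @param config [focus_score()] config; must contain a numeric `threshold`
#'   (calibrate one with [calibrate_threshold()]).
#' @param report_csv optional path for the report CSV.
#' @return list with `kept` (list of fields), `report` (data frame).
#' @export
qc_batch <- function(fields, config = list(), report_csv = NULL) {
  if (length(fields) == 0) stop_phenoscreen("qc_batch: no fields")
  if (is.null(config$threshold) || is.na(config$threshold)) {
    stop_phenoscreen("qc_batch needs an explicit threshold; run calibrate_threshold() ",
                     "or set config$threshold")
  }
  reports <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    reports[[i]] <- tryCatch(focus_score(fields[[i]], config),
      error = function(e) stop_phenoscreen("QC failed on field '",
                                           fields[[i]]$id, "': ", conditionMessage(e)))
  }
  report <- do.call(rbind, reports)
  if (!is.null(report_csv)) utils::write.csv(report, report_csv, row.names = FALSE)
  list(kept = fields[report$keep], report = report)
}
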